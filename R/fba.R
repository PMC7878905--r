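# Bounds at or above this are treated as "infinite"; optima approaching it
# are reported as unbounded rather than silently truncated.
.FBA_BIG <- 1e6

#' Construct a metabolic model
#'
#' Minimal constraint-based model: metabolites with compartment tags
#' (\code{[c]} cytosol, \code{[u]} urine, \code{[bc]} blood), reactions with
#' stoichiometry, flux bounds, associated genes, and an organ tag. Urine
#' excretion reactions are named \code{EX_<met>[u]} and blood demand
#' reactions \code{DM_<met>[bc]}.
#'
#' @param id Model id.
#' @param metabolites data.frame with columns \code{id}, \code{compartment}.
#' @param reactions List of reactions, each a list with \code{id},
#'   \code{metabolites} (named numeric stoichiometry), \code{lb}, \code{ub},
#'   \code{genes} (character), \code{organ}.
#' @return Object of class \code{MetabolicModel} with the stoichiometric
#'   matrix in \code{$S} (metabolites x reactions).
#' @export
metabolic_model <- function(id, metabolites, reactions) {
  met_ids <- metabolites$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction id")
  S <- matrix(0, length(met_ids), length(reactions),
              dimnames = list(met_ids, rxn_ids))
  for (r in reactions) {
    unknown <- setdiff(names(r$metabolites), met_ids)
    if (length(unknown))
      stop("reaction ", r$id, " references undeclared metabolite: ",
           paste(unknown, collapse = ", "))
    if (r$lb > r$ub) stop("reaction ", r$id, " has lb > ub")
    S[names(r$metabolites), r$id] <- unlist(r$metabolites)
  }
  names(reactions) <- rxn_ids
  structure(list(id = id, metabolites = metabolites,
                 reactions = reactions, S = S),
            class = "MetabolicModel")
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel '%s': %d metabolites, %d reactions\n",
              x$id, nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Read a metabolic model from JSON
#'
#' Schema (version 1): object with \code{schema_version}, \code{id},
#' \code{metabolites} (array of \{id, compartment\}) and \code{reactions}
#' (array of \{id, metabolites (object), lb, ub, genes, organ\}).
#'
#' @param path JSON file path.
#' @return A validated \code{MetabolicModel}.
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(j$metabolites, `[[`, "", "id"),
    compartment = vapply(j$metabolites, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  rxns <- lapply(j$reactions, function(r) list(
    id = r$id,
    metabolites = unlist(r$metabolites),
    lb = as.numeric(r$lb),
    ub = if (is.character(r$ub) || is.null(r$ub)) Inf else as.numeric(r$ub),
    genes = as.character(unlist(r$genes)),
    organ = if (is.null(r$organ)) "body" else r$organ))
  metabolic_model(j$id, mets, rxns)
}

#' Write a metabolic model to JSON
#'
#' @param model A \code{MetabolicModel}.
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  j <- list(
    schema_version = 1,
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, ])),
    reactions = lapply(unname(model$reactions), function(r) list(
      id = r$id, metabolites = as.list(r$metabolites),
      lb = r$lb, ub = if (is.infinite(r$ub)) "inf" else r$ub,
      genes = r$genes, organ = r$organ)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Maximize the flux through one reaction
#'
#' Solves the linear program max v_obj subject to S v = 0 and
#' lb <= v <= ub. Infinite bounds are realized as a large explicit bound;
#' an optimum at that bound is reported as \code{"unbounded"} rather than
#' as a flux value.
#'
#' @param model A \code{MetabolicModel}.
#' @param objective Reaction id to maximize.
#' @return \code{FluxResult} list: \code{objective}, \code{status}
#'   (\code{optimal}, \code{infeasible}, \code{unbounded}, or
#'   \code{failed}), \code{value} (present iff optimal), \code{fluxes}
#'   (full flux vector at the optimum), \code{tolerance}.
#' @export
fba_maximize <- function(model, objective) {
  rxn_ids <- names(model$reactions)
  if (!objective %in% rxn_ids) stop("unknown objective reaction: ", objective)
  a <- numeric(length(rxn_ids)); a[match(objective, rxn_ids)] <- 1
  sol <- .solve_lp(model, a)
  tol <- 1e-9
  if (sol$status != "optimal")
    return(list(objective = objective, status = sol$status, value = NULL,
                fluxes = NULL, tolerance = tol))
  value <- sol$v[objective]
  if (value >= 0.5 * .FBA_BIG)
    return(list(objective = objective, status = "unbounded", value = NULL,
                fluxes = NULL, tolerance = tol))
  list(objective = objective, status = "optimal", value = unname(value),
       fluxes = sol$v, tolerance = tol)
}

# Maximize a'v subject to S v = 0, lb <= v <= ub.
# Fixed variables (lb == ub) are substituted out; the rest is shifted to
# the non-negative form x = v - lb, upper bounds become slack rows, and
# the program goes through the two-phase tableau simplex below.
.solve_lp <- function(model, a) {
  rxn_ids <- names(model$reactions)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  lb[lb < -.FBA_BIG] <- -.FBA_BIG
  ub[ub > .FBA_BIG] <- .FBA_BIG
  S <- model$S
  fixed <- (ub - lb) < 1e-12
  v_full <- stats::setNames(rep(NA_real_, length(rxn_ids)), rxn_ids)
  v_full[fixed] <- lb[fixed]
  free <- which(!fixed)
  rhs <- -as.vector(S[, fixed, drop = FALSE] %*% lb[fixed])
  if (length(free) == 0) {
    if (any(abs(rhs) > 1e-9)) return(list(status = "infeasible"))
    return(list(status = "optimal", v = v_full))
  }
  Sf <- S[, free, drop = FALSE]
  b_eq <- rhs - as.vector(Sf %*% lb[free])
  nf <- length(free)
  # standard form: [Sf 0; I I] [x; s] = [b_eq; ub - lb], x, s >= 0
  A <- rbind(cbind(Sf, matrix(0, nrow(Sf), nf)),
             cbind(diag(nf), diag(nf)))
  b <- c(b_eq, (ub - lb)[free])
  cvec <- c(a[free], rep(0, nf))
  sol <- .lp_simplex(cvec, A, b)
  if (sol$status != "optimal") return(list(status = sol$status))
  v_full[free] <- sol$x[seq_len(nf)] + lb[free]
  list(status = "optimal", v = v_full)
}

# Two-phase primal simplex (dense tableau, Bland's rule, so no cycling)
# for max c'x s.t. A x = b, x >= 0. All problems handed here are bounded
# by construction (explicit upper-bound rows), so phase 2 cannot be
# unbounded; a failure to pivot is reported as "failed".
.lp_simplex <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, ]; b[neg] <- -b[neg]
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  pivot <- function(Tab, basis, obj, allowed) {
    ncolT <- ncol(Tab)
    repeat {
      cb <- obj[basis]
      red <- as.vector(cb %*% Tab[, -ncolT, drop = FALSE]) -
        obj[seq_len(ncolT - 1)]
      enter <- which(red > tol & allowed)
      if (!length(enter))
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(enter)
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[pos, ncolT] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      i <- cand[which.min(basis[cand])]
      Tab[i, ] <- Tab[i, ] / Tab[i, j]
      upd <- which(abs(Tab[, j]) > 0 & seq_len(nrow(Tab)) != i)
      for (r in upd) Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
      basis[i] <- j
    }
  }
  # pivot() minimizes its objective (enters where z_j - c_j > 0)
  # phase 1: minimize the sum of artificials
  obj1 <- c(rep(0, n), rep(1, m))
  ph1 <- pivot(Tab, basis, obj1, allowed = rep(TRUE, n + m))
  if (ph1$status != "optimal") return(list(status = "failed"))
  Tab <- ph1$Tab; basis <- ph1$basis
  if (sum(Tab[basis > n, ncol(Tab)]) > 1e-7)
    return(list(status = "infeasible"))
  # drive any zero-level artificial out of the basis
  for (i in which(basis > n)) {
    row <- Tab[i, seq_len(n)]
    j <- which(abs(row) > tol)
    if (length(j)) {
      j <- j[1]
      Tab[i, ] <- Tab[i, ] / Tab[i, j]
      upd <- which(abs(Tab[, j]) > 0 & seq_len(nrow(Tab)) != i)
      for (r in upd) Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
      basis[i] <- j
    }
  }
  # phase 2: maximize c'x = minimize -c'x over the original columns only
  obj2 <- c(-cvec, rep(0, m))
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- pivot(Tab, basis, obj2, allowed)
  if (ph2$status != "optimal") return(list(status = "failed"))
  x <- numeric(n)
  keep <- ph2$basis <= n
  x[ph2$basis[keep]] <- ph2$Tab[keep, ncol(ph2$Tab)]
  list(status = "optimal", x = x)
}

.gene_reactions <- function(model, gene) {
  hits <- names(Filter(function(r) gene %in% r$genes, model$reactions))
  if (length(hits) == 0) stop("gene not present in model: ", gene)
  hits
}

.check_no_isozyme <- function(model, gene) {
  for (rid in .gene_reactions(model, gene)) {
    others <- setdiff(model$reactions[[rid]]$genes, gene)
    if (length(others))
      stop("gene ", gene, " shares reaction ", rid, " with isozyme(s) ",
           paste(others, collapse = ", "),
           "; knockout effect would be masked, refusing")
  }
  invisible(TRUE)
}

#' Knock out a gene
#'
#' Sets the flux bounds of every reaction associated with the gene, in all
#' organ tags, to zero. Genes sharing a reaction with an isozyme are
#' refused: the remaining enzyme would mask the knockout.
#'
#' @param model A \code{MetabolicModel}.
#' @param gene Gene id present in the model, without isozymes.
#' @return The knockout \code{MetabolicModel}.
#' @export
apply_knockout <- function(model, gene) {
  .check_no_isozyme(model, gene)
  for (rid in .gene_reactions(model, gene)) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

#' Constrain a model to its healthy enzyme throughput
#'
#' The healthy reference fixes the gene's reactions at their maximal joint
#' activity: the summed flux of all the gene's reactions (across organs) is
#' maximized, and each reaction is then fixed at its value in that optimum.
#' A sequential mode maximizes and fixes one reaction at a time instead.
#'
#' @param model A \code{MetabolicModel}.
#' @param gene Gene id (no isozymes).
#' @param mode \code{"joint"} (default) or \code{"sequential"}.
#' @return Constrained \code{MetabolicModel}; attribute
#'   \code{"zero_flux"} is \code{TRUE} when the gene carries no feasible
#'   flux (fixed at 0).
#' @export
healthy_reference <- function(model, gene, mode = c("joint", "sequential")) {
  mode <- match.arg(mode)
  .check_no_isozyme(model, gene)
  rids <- .gene_reactions(model, gene)
  if (mode == "joint") {
    opt <- .fba_maximize_combined(model, rids)
    if (is.null(opt)) stop("healthy-reference maximization infeasible")
    for (rid in rids) {
      model$reactions[[rid]]$lb <- unname(opt[rid])
      model$reactions[[rid]]$ub <- unname(opt[rid])
    }
    attr(model, "zero_flux") <- all(abs(opt[rids]) < 1e-9)
  } else {
    vals <- numeric(0)
    for (rid in rids) {
      res <- fba_maximize(model, rid)
      if (res$status != "optimal")
        stop("healthy-reference maximization ", res$status, " for ", rid)
      model$reactions[[rid]]$lb <- unname(res$value)
      model$reactions[[rid]]$ub <- unname(res$value)
      vals[rid] <- res$value
    }
    attr(model, "zero_flux") <- all(abs(vals) < 1e-9)
  }
  model
}

# maximize the summed flux of several reactions; returns named flux vector
.fba_maximize_combined <- function(model, rids) {
  rxn_ids <- names(model$reactions)
  a <- numeric(length(rxn_ids)); a[match(rids, rxn_ids)] <- 1
  sol <- .solve_lp(model, a)
  if (sol$status != "optimal") return(NULL)
  sol$v
}

.open_target <- function(model, metabolite, compartment) {
  comp_tag <- if (compartment == "urine") "u" else "bc"
  species <- paste0(metabolite, "[", comp_tag, "]")
  rid <- if (compartment == "urine") paste0("EX_", species)
         else paste0("DM_", species)
  if (!rid %in% names(model$reactions)) {
    if (!species %in% model$metabolites$id)
      stop("metabolite ", species, " not in model; cannot create ", rid)
    sto <- stats::setNames(-1, species)
    model$reactions[[rid]] <- list(id = rid, metabolites = sto,
                                   lb = 0, ub = Inf, genes = character(0),
                                   organ = "body")
    model$S <- cbind(model$S, stats::setNames(numeric(nrow(model$S)), NULL))
    colnames(model$S)[ncol(model$S)] <- rid
    model$S[species, rid] <- -1
  }
  model$reactions[[rid]]$lb <- 0
  model$reactions[[rid]]$ub <- Inf
  list(model = model, target = rid)
}

#' Predict the direction of a metabolite change under gene knockout
#'
#' Opens the urine excretion (\code{EX_<met>[u]}) or blood demand
#' (\code{DM_<met>[bc]}) reaction to [0, Inf), maximizes it under the
#' healthy-reference model and under the knockout model, and calls the
#' direction of change: up if KO - healthy exceeds
#' \code{tolerance * max(1, |healthy|)} (with a 1e-9 absolute floor), down
#' if below the negative of that, unchanged otherwise.
#'
#' @param model A \code{MetabolicModel}.
#' @param gene Gene to knock out (no isozymes).
#' @param metabolite Metabolite base id (without compartment tag).
#' @param compartment \code{"urine"} or \code{"blood"}.
#' @param tolerance Relative tolerance for the direction call.
#' @return \code{KnockoutPrediction} list: gene, metabolite, compartment,
#'   direction (\code{"down"}, \code{"unchanged"}, \code{"up"}),
#'   healthy_flux, knockout_flux.
#' @export
predict_direction <- function(model, gene, metabolite,
                              compartment = c("urine", "blood"),
                              tolerance = 1e-6) {
  compartment <- match.arg(compartment)
  opened <- .open_target(model, metabolite, compartment)
  healthy <- fba_maximize(healthy_reference(opened$model, gene),
                          opened$target)
  ko <- fba_maximize(apply_knockout(opened$model, gene), opened$target)
  if (healthy$status == "unbounded" && ko$status == "unbounded")
    stop("target flux unbounded in both conditions; direction undefined")
  for (res in list(healthy = healthy, ko = ko))
    if (!res$status %in% c("optimal"))
      stop("target maximization not optimal (", res$status, ")")
  diff <- ko$value - healthy$value
  thr <- max(tolerance * max(1, abs(healthy$value)), 1e-9)
  direction <- if (diff > thr) "up" else if (diff < -thr) "down"
               else "unchanged"
  structure(list(gene = gene, metabolite = metabolite,
                 compartment = compartment, direction = direction,
                 healthy_flux = healthy$value, knockout_flux = ko$value,
                 tolerance = tolerance),
            class = "KnockoutPrediction")
}

#' @export
print.KnockoutPrediction <- function(x, ...) {
  arrow <- c(up = "↑", down = "↓", unchanged = "=")[x$direction]
  cat(sprintf("KO %s / %s [%s]: healthy %.4g -> KO %.4g (%s)\n",
              x$gene, x$metabolite, x$compartment,
              x$healthy_flux, x$knockout_flux, arrow))
  invisible(x)
}

#' Exact binomial test of prediction-observation concordance
#'
#' Counts positions where the predicted and observed directions agree and
#' computes the exact one-sided upper-tail binomial probability
#' P(X >= n_match | n, null_p) by direct summation over outcomes.
#'
#' @param predictions,observations Equal-length character vectors of
#'   directions.
#' @param null_p Chance agreement probability under the null (e.g. 1/3 for
#'   a three-outcome direction call).
#' @return List: \code{n_match}, \code{n}, \code{p}.
#' @export
concordance_binomial_test <- function(predictions, observations,
                                      null_p = 1 / 3) {
  if (length(predictions) != length(observations))
    stop("prediction and observation vectors differ in length")
  if (null_p <= 0 || null_p >= 1) {
    if (null_p == 1) return(list(n_match = sum(predictions == observations),
                                 n = length(predictions), p = 1))
    stop("null_p must be in (0, 1)")
  }
  n <- length(predictions)
  n_match <- sum(predictions == observations)
  ks <- n_match:n
  p <- sum(choose(n, ks) * null_p^ks * (1 - null_p)^(n - ks))
  list(n_match = n_match, n = n, p = min(p, 1))
}
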