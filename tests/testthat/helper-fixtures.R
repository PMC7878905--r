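# Shared fixtures and independent oracles, built in code at test time.

# small genotype matrix with known counts
tiny_genotypes <- function() {
  d <- rbind(S1 = c(0, 0, 2), S2 = c(1, 0, 0), S3 = c(0, 1, 0),
             S4 = c(2, 0, 0), S5 = c(0, 0, 0), S6 = c(0, NA, 0))
  colnames(d) <- c("v1", "v2", "v3")
  genotype_data(d)
}

tiny_annotations <- function() {
  data.frame(variant_id = c("v1", "v2", "v3"),
             gene = c("GENEA", "GENEA", "GENEB"),
             consequence = c("nonsynonymous", "stop gain", "synonymous"),
             stringsAsFactors = FALSE)
}

# raw metabolite matrix from a common profile times per-sample dilution,
# with median(dilution) == 1 so PQN recovers the profile exactly
profile_dilution_matrix <- function(n = 40, m = 8, seed = 1) {
  set.seed(seed)
  profile <- rlnorm(m, meanlog = 1)
  d <- rlnorm(n, 0, 0.5)
  d <- d / stats::median(d)
  values <- outer(d, profile)
  colnames(values) <- paste0("met", seq_len(m))
  rownames(values) <- paste0("S", seq_len(n))
  list(matrix = metabolite_matrix(values, state = "raw"),
       profile = matrix(rep(profile, each = n), n, m), dilution = d)
}

# independent LP oracle: enumerate all basic solutions of
# max c'v s.t. S v = 0, lb <= v <= ub by fixing subsets of variables at a
# bound and solving the equality system for the rest; keeps the best
# feasible candidate. Exponential, fine for <= 8 reactions.
lp_vertex_oracle <- function(S, lb, ub, cvec) {
  n <- ncol(S)
  best <- NULL
  bounds <- rbind(lb, ub)
  # iterate over which variables are free (solved from S) vs at a bound
  for (free_mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(free_mask, 2^(seq_len(n) - 1)) > 0)
    fixed <- setdiff(seq_len(n), free)
    if (length(fixed) == 0) next
    combos <- expand.grid(rep(list(1:2), length(fixed)))
    for (ci in seq_len(nrow(combos))) {
      v <- rep(NA_real_, n)
      for (t in seq_along(fixed))
        v[fixed[t]] <- bounds[combos[ci, t], fixed[t]]
      if (length(free)) {
        Sf <- S[, free, drop = FALSE]
        rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
        sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
      }
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      val <- sum(cvec * v)
      if (is.null(best) || val > best) best <- val
    }
  }
  best
}

ko_gene_for <- c(degrader = "GENE_DEG", producer = "GENE_PROD",
                 capacity_limited = "GENE_CAP")
ko_met_for <- c(degrader = "A", producer = "M", capacity_limited = "M")
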