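#' Construct a metabolite intensity matrix
#'
#' Container for urine metabolite intensities as they move through quality
#' control: raw intensities, outlier-masked, dilution-normalized
#' (probabilistic quotient), and finally rank-based inverse-normal
#' transformed values. The state flag only moves forward through
#' \code{raw -> outlier-masked -> pqn-normalized -> transformed}; each
#' operation checks that its input is in the expected state.
#'
#' @param values Numeric matrix, samples in rows and metabolites in columns,
#'   with row and column names. \code{NA} encodes a missing measurement.
#'   Values must be non-negative before transformation.
#' @param pathway Optional character vector of super-pathway labels
#'   (e.g. \code{"amino acid"}, \code{"peptide"}, \code{"lipid-fatty acid"}),
#'   one per metabolite, named by metabolite id.
#' @param state One of \code{"raw"}, \code{"outlier-masked"},
#'   \code{"pqn-normalized"}, \code{"transformed"}.
#' @return An object of class \code{MetaboliteMatrix}.
#' @export
metabolite_matrix <- function(values, pathway = NULL, state = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  state <- match.arg(state, .met_states)
  if (state != "transformed" && any(values < 0, na.rm = TRUE))
    stop("intensities must be non-negative before transformation")
  if (is.null(pathway)) {
    pathway <- rep(NA_character_, ncol(values))
    names(pathway) <- colnames(values)
  } else {
    if (is.null(names(pathway))) names(pathway) <- colnames(values)
    pathway <- pathway[colnames(values)]
  }
  structure(list(values = values, pathway = pathway, state = state),
            class = "MetaboliteMatrix")
}

.met_states <- c("raw", "outlier-masked", "pqn-normalized", "transformed")

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  cat(sprintf("MetaboliteMatrix: %d samples x %d metabolites [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.MetaboliteMatrix <- function(x) dim(x$values)

.check_state <- function(m, expected) {
  if (!inherits(m, "MetaboliteMatrix")) stop("expected a MetaboliteMatrix")
  if (!m$state %in% expected)
    stop(sprintf("operation requires state %s, got '%s'",
                 paste(sQuote(expected), collapse = " or "), m$state))
}

#' Mask outlying metabolite values
#'
#' Per metabolite, values more than \code{k} standard deviations from the
#' metabolite mean are set to missing. Mean and SD are computed over the
#' observed values of that metabolite in a single pass, with the candidate
#' value included. Metabolites with zero SD (constant columns) mask nothing.
#' The comparison is strict: a value at exactly \code{k} SD is retained.
#'
#' @param m A \code{MetaboliteMatrix} in state \code{"raw"}.
#' @param k Positive multiple of the SD beyond which a value is an outlier.
#' @return The matrix with outliers set to \code{NA}, state
#'   \code{"outlier-masked"}.
#' @export
mask_outliers <- function(m, k = 5) {
  .check_state(m, "raw")
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be positive")
  v <- m$values
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    if (is.na(sdv[j]) || sdv[j] == 0) next
    out <- !is.na(v[, j]) & abs(v[, j] - mu[j]) > k * sdv[j]
    v[out, j] <- NA
  }
  metabolite_matrix(v, m$pathway, state = "outlier-masked")
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution differences (urine concentration varies with
#' hydration). The reference spectrum is the per-metabolite median over all
#' samples, restricted to metabolites with a missing fraction below
#' \code{ref_missing_max}. Each sample's quotient is the median of
#' \code{x[i, m] / ref[m]} over the reference metabolites observed in that
#' sample, and every value in the sample is divided by that quotient.
#'
#' @param m A \code{MetaboliteMatrix} in state \code{"outlier-masked"}.
#' @param ref_missing_max Maximum missing fraction (strict) for a metabolite
#'   to enter the reference spectrum.
#' @return Normalized \code{MetaboliteMatrix}, state \code{"pqn-normalized"},
#'   with the per-sample quotients in attribute \code{"quotients"}.
#' @export
pqn_normalize <- function(m, ref_missing_max = 0.01) {
  .check_state(m, "outlier-masked")
  v <- m$values
  miss_frac <- colMeans(is.na(v))
  ref_idx <- which(miss_frac < ref_missing_max)
  if (length(ref_idx) == 0)
    stop("no metabolite satisfies the reference missingness criterion")
  ref <- apply(v[, ref_idx, drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (any(ref <= 0)) stop("non-positive reference median")
  q <- apply(sweep(v[, ref_idx, drop = FALSE], 2, ref, "/"), 1,
             stats::median, na.rm = TRUE)
  if (any(!is.na(q) & q <= 0)) stop("non-positive probabilistic quotient")
  out <- metabolite_matrix(v / q, m$pathway, state = "pqn-normalized")
  attr(out, "quotients") <- q
  out
}

#' Drop columns observed in too few samples
#'
#' Metabolites (or ratios) quantified in fewer than \code{min_n} samples are
#' removed; small observation counts make the rank-based tests unstable.
#' Column order is otherwise preserved.
#'
#' @param m A \code{MetaboliteMatrix} or \code{RatioMatrix}.
#' @param min_n Minimum number of non-missing observations (inclusive).
#' @return Object of the same class with under-observed columns removed.
#' @export
filter_min_observations <- function(m, min_n = 300) {
  if (inherits(m, "MetaboliteMatrix")) {
    keep <- colSums(!is.na(m$values)) >= min_n
    out <- metabolite_matrix(m$values[, keep, drop = FALSE],
                             m$pathway[keep], state = m$state)
    attr(out, "quotients") <- attr(m, "quotients")
    return(out)
  }
  if (inherits(m, "RatioMatrix")) {
    keep <- colSums(!is.na(m$values)) >= min_n
    return(structure(list(values = m$values[, keep, drop = FALSE],
                          pairs = m$pairs[keep, , drop = FALSE]),
                     class = "RatioMatrix"))
  }
  stop("expected a MetaboliteMatrix or RatioMatrix")
}

#' Rank-based inverse normal transformation
#'
#' Observed values are replaced by normal quantiles of their rank:
#' \code{qnorm((rank - 0.5) / n_observed)}, with ties given average rank.
#' Missing values stay missing. The offset 0.5 makes the transformed values
#' symmetric around zero for tie-free input.
#'
#' @param x Numeric vector, possibly with \code{NA}.
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) stop("inverse normal transform needs at least 2 observed values")
  out <- rep(NA_real_, length(x))
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Apply the inverse normal transform to every metabolite
#'
#' @param m A \code{MetaboliteMatrix} (any state before \code{"transformed"}).
#' @return \code{MetaboliteMatrix} in state \code{"transformed"}.
#' @export
int_transform <- function(m) {
  .check_state(m, setdiff(.met_states, "transformed"))
  v <- apply(m$values, 2, inverse_normal_transform)
  dimnames(v) <- dimnames(m$values)
  metabolite_matrix(v, m$pathway, state = "transformed")
}

#' Pairwise metabolite ratios
#'
#' Builds one ratio per unordered pair of eligible metabolites (those whose
#' super-pathway is in \code{include_pathways}). Orientation is fixed
#' lexicographically by metabolite id (numerator sorts first); the tests
#' downstream are orientation-invariant under the inverse normal transform,
#' and reports carry both member names. A ratio is missing for a sample
#' whenever either member is missing or the denominator is zero.
#'
#' @param m A \code{MetaboliteMatrix} in state \code{"pqn-normalized"}.
#' @param include_pathways Character vector of super-pathway labels to
#'   include, or \code{NULL} for all metabolites.
#' @return A \code{RatioMatrix}: \code{$values} (samples x pairs) and
#'   \code{$pairs} (ratio id, members, member pathways).
#' @export
build_ratio_matrix <- function(m, include_pathways = NULL) {
  .check_state(m, "pqn-normalized")
  if (!is.null(include_pathways)) {
    if (length(include_pathways) == 0) stop("empty pathway selection")
    elig <- which(m$pathway %in% include_pathways)
  } else elig <- seq_len(ncol(m$values))
  if (length(elig) < 2) stop("need at least 2 eligible metabolites")
  ids <- sort(colnames(m$values)[elig])
  pr <- utils::combn(ids, 2)
  v <- m$values
  num <- v[, pr[1, ], drop = FALSE]
  den <- v[, pr[2, ], drop = FALSE]
  den[!is.na(den) & den == 0] <- NA
  ratios <- num / den
  colnames(ratios) <- paste(pr[1, ], pr[2, ], sep = "/")
  pairs <- data.frame(ratio_id = colnames(ratios),
                      met_a = pr[1, ], met_b = pr[2, ],
                      pathway_a = unname(m$pathway[pr[1, ]]),
                      pathway_b = unname(m$pathway[pr[2, ]]),
                      stringsAsFactors = FALSE)
  structure(list(values = ratios, pairs = pairs), class = "RatioMatrix")
}

#' @export
print.RatioMatrix <- function(x, ...) {
  cat(sprintf("RatioMatrix: %d samples x %d ratios\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
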