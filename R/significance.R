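#' Bonferroni significance threshold
#'
#' Divides the overall type-I error across genes, phenotypes, and the two
#' aggregation tests: \code{alpha / (n_genes * n_phenotypes * n_tests)}.
#' With 11,552 genes, 1487 metabolites and 2 tests this gives the
#' study-wide 1.46e-9 level for single metabolites; with one phenotype it
#' gives the suggestive level 2.2e-6.
#'
#' @param alpha Overall type-I error (default 0.05).
#' @param n_genes,n_phenotypes,n_tests Counts (all >= 1).
#' @return List: \code{threshold} (full precision) and \code{printed}
#'   (3 significant digits).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes, n_phenotypes = 1,
                                 n_tests = 2) {
  if (any(c(n_genes, n_phenotypes, n_tests) < 1)) stop("counts must be >= 1")
  th <- alpha / (n_genes * n_phenotypes * n_tests)
  list(threshold = th, printed = signif(th, 3))
}

#' p-gain of a metabolite ratio
#'
#' Information gained by testing the ratio instead of its members:
#' \code{min(p_A, p_B) / p_ratio}. Computed in log space so that extreme
#' p-values (down to the double-precision floor) do not overflow.
#'
#' @param p_a,p_b p-values of the two member metabolites, in (0, 1].
#' @param p_ratio p-value of the ratio, in (0, 1].
#' @return List: \code{p_gain} (full precision; \code{Inf} if the ratio
#'   overflows the double range), \code{log10_p_gain}, and \code{printed}
#'   (2 significant digits).
#' @export
p_gain <- function(p_a, p_b, p_ratio) {
  for (p in c(p_a, p_b, p_ratio))
    if (!is.finite(p) || p <= 0 || p > 1) stop("p-values must be in (0, 1]")
  lg <- log10(min(p_a, p_b)) - log10(p_ratio)
  pg <- 10^lg
  list(p_gain = pg, log10_p_gain = lg, printed = signif(pg, 2))
}

#' Retention threshold for ratio findings
#'
#' A ratio association is only retained when its p-gain exceeds 10 times
#' the number of evaluated ratios, guarding against p-gains expected by
#' chance alone.
#'
#' @param n_ratios Number of evaluated ratios (>= 1).
#' @return Numeric threshold \code{10 * n_ratios}.
#' @export
p_gain_retention_threshold <- function(n_ratios) {
  if (n_ratios < 1) stop("n_ratios must be >= 1")
  10 * n_ratios
}

#' Split association results into significant and suggestive tables
#'
#' A record is significant when either test's p-value is below
#' \code{threshold} (and, for ratio records carrying a \code{p_gain}
#' column, the p-gain clears \code{pgain_threshold}); it is suggestive
#' when either p-value is below \code{suggestive_threshold}. Each
#' significant row is labeled \code{"B"}, \code{"S"}, or \code{"Both"}
#' according to which tests clear the threshold.
#'
#' @param results data.frame with columns \code{p_burden} and \code{p_skat}
#'   (and optionally \code{p_gain}).
#' @param threshold Study-wide significance threshold.
#' @param suggestive_threshold Single-phenotype threshold.
#' @param pgain_threshold Retention threshold applied when a \code{p_gain}
#'   column is present; \code{NULL} to skip.
#' @return List: \code{significant} (with \code{significant_test} label)
#'   and \code{suggestive} data.frames.
#' @export
assemble_results <- function(results, threshold, suggestive_threshold,
                             pgain_threshold = NULL) {
  stopifnot(all(c("p_burden", "p_skat") %in% names(results)))
  hit_b <- results$p_burden < threshold
  hit_s <- results$p_skat < threshold
  sig <- hit_b | hit_s
  if (!is.null(pgain_threshold) && "p_gain" %in% names(results))
    sig <- sig & results$p_gain > pgain_threshold
  sig_tab <- results[sig, , drop = FALSE]
  sig_tab$significant_test <- ifelse(hit_b[sig] & hit_s[sig], "Both",
                              ifelse(hit_b[sig], "B", "S"))
  sugg <- results[(results$p_burden < suggestive_threshold |
                   results$p_skat < suggestive_threshold), , drop = FALSE]
  list(significant = sig_tab, suggestive = sugg)
}
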