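#' Construct an expression container
#'
#' @param values Non-negative expression matrix (TPM-like), genes in rows,
#'   samples in columns, with dimnames.
#' @param labels Character vector of tissue/cell-type labels, one per
#'   sample (at least 2 distinct labels).
#' @return Object of class \code{ExpressionData}.
#' @export
expression_data <- function(values, labels) {
  values <- as.matrix(values)
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (length(unique(labels)) < 2) stop("need at least 2 distinct labels")
  if (any(values < 0, na.rm = TRUE)) stop("expression must be non-negative")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  structure(list(values = values, labels = as.character(labels)),
            class = "ExpressionData")
}

#' @export
print.ExpressionData <- function(x, ...) {
  cat(sprintf("ExpressionData: %d genes x %d samples, %d labels\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' Tissue- or cell-type-specific expression gene sets
#'
#' For each label, every gene's specificity is scored by the t-statistic of
#' the label-indicator coefficient in a linear model of log10(x + 1)
#' expression across all samples (equivalently a pooled-variance two-group
#' t comparing the focal label to the rest). The top \code{ceiling(fraction
#' * G)} genes per label form its specific-expression set. Ties at the
#' boundary are broken by gene-id order (deterministic, flagged).
#'
#' @param expr An \code{ExpressionData} with >= 2 samples per label.
#' @param fraction Fraction of genes per set (default 0.10, the top decile).
#' @return Named list of character vectors (gene sets per label), with the
#'   per-label t-statistic matrix in attribute \code{"t_stats"}.
#' @export
specific_expression_sets <- function(expr, fraction = 0.10) {
  labs <- unique(expr$labels)
  v <- log10(expr$values + 1)
  G <- nrow(v); n <- ncol(v)
  n_top <- ceiling(fraction * G)
  tstats <- matrix(NA_real_, G, length(labs),
                   dimnames = list(rownames(v), labs))
  for (lb in labs) {
    in_g <- expr$labels == lb
    n1 <- sum(in_g); n0 <- n - n1
    if (n1 < 2) stop("label '", lb, "' has fewer than 2 samples")
    m1 <- rowMeans(v[, in_g, drop = FALSE])
    m0 <- rowMeans(v[, !in_g, drop = FALSE])
    ss1 <- rowSums((v[, in_g, drop = FALSE] - m1)^2)
    ss0 <- rowSums((v[, !in_g, drop = FALSE] - m0)^2)
    sp2 <- (ss1 + ss0) / (n - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    if (any(se == 0 & m1 == m0))
      se[se == 0 & m1 == m0] <- Inf  # constant gene: t = 0
    if (any(se == 0)) stop("degenerate (zero-variance) gene for label ", lb)
    tstats[, lb] <- (m1 - m0) / se
  }
  sets <- lapply(labs, function(lb) {
    ord <- order(-tstats[, lb], rownames(v))
    rownames(v)[ord[seq_len(n_top)]]
  })
  names(sets) <- labs
  attr(sets, "t_stats") <- tstats
  sets
}

#' Z-scored mean-expression profile of selected genes
#'
#' Per gene: mean log10(x + 1) expression per label, standardized across
#' labels to mean 0 and SD 1 (the usual heatmap convention). Constant genes
#' get an all-zero row.
#'
#' @param expr An \code{ExpressionData}.
#' @param genes Gene ids to profile.
#' @return Matrix (genes x labels) of z-scores.
#' @export
zscore_profile <- function(expr, genes) {
  labs <- unique(expr$labels)
  if (length(labs) < 2) stop("need more than one label")
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) stop("genes absent: ", paste(missing, collapse = ", "))
  v <- log10(expr$values[genes, , drop = FALSE] + 1)
  mu <- sapply(labs, function(lb)
    rowMeans(v[, expr$labels == lb, drop = FALSE]))
  mu <- matrix(mu, nrow = length(genes),
               dimnames = list(genes, labs))
  z <- t(apply(mu, 1, function(row) {
    s <- stats::sd(row)
    if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
  }))
  dimnames(z) <- dimnames(mu)
  z
}

#' Gene-set database
#'
#' Named gene sets over a fixed universe. Sets smaller than \code{min_size}
#' are removed; genes outside the universe are dropped from sets.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of all eligible gene ids.
#' @param min_size Minimum retained set size (default 5).
#' @return Object of class \code{GeneSetDB}.
#' @export
gene_set_db <- function(sets, universe, min_size = 5) {
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  structure(list(sets = sets, universe = universe, min_size = min_size),
            class = "GeneSetDB")
}

#' Monte-Carlo gene-set enrichment
#'
#' The observed overlap between a query gene list of size k and each set is
#' compared to overlaps of random size-k gene lists drawn uniformly without
#' replacement from the universe. The p-value uses the add-one rule
#' \code{(1 + #draws with overlap >= observed) / (1 + n_draws)}, so it is
#' never zero. With uniform draws this converges to the hypergeometric
#' upper tail.
#'
#' @param query Character vector of query genes (subset of the universe).
#' @param db A \code{GeneSetDB}.
#' @param n_draws Number of random draws (default 1e5; raise for final
#'   analyses).
#' @param seed Integer seed for the draws.
#' @return data.frame per set: observed and expected overlap, odds ratio
#'   (with continuity-correction flag), Monte-Carlo p, n_draws, seed.
#' @export
mc_enrichment <- function(query, db, n_draws = 1e5, seed = 1) {
  query <- unique(query)
  if (length(query) < 1) stop("empty query")
  outside <- setdiff(query, db$universe)
  if (length(outside))
    stop("query genes absent from universe: ",
         paste(outside, collapse = ", "))
  N <- length(db$universe); k <- length(query)
  set.seed(seed)
  masks <- lapply(db$sets, function(s) db$universe %in% s)
  obs <- vapply(masks, function(msk) sum(db$universe[msk] %in% query), 1L)
  exceed <- integer(length(db$sets))
  # draws in blocks: one matrix of uniform k-subsets, overlaps by masked sums
  block <- 20000L
  done <- 0L
  while (done < n_draws) {
    nb <- min(block, n_draws - done)
    idx <- matrix(0L, nb, k)
    for (d in seq_len(nb)) idx[d, ] <- sample.int(N, k)
    for (j in seq_along(masks)) {
      ov <- rowSums(matrix(masks[[j]][idx], nb, k))
      exceed[j] <- exceed[j] + sum(ov >= obs[j])
    }
    done <- done + nb
  }
  K <- vapply(db$sets, length, 1L)
  or <- mapply(function(a, Ksz) enrichment_odds_ratio(a, k, Ksz, N)$or,
               obs, K)
  flag <- mapply(function(a, Ksz)
    enrichment_odds_ratio(a, k, Ksz, N)$continuity_corrected, obs, K)
  data.frame(set = names(db$sets), observed = obs,
             expected = k * K / N, odds_ratio = or,
             continuity_corrected = flag,
             p = (1 + exceed) / (1 + n_draws),
             n_draws = n_draws, seed = seed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment odds ratio from the 2x2 membership table
#'
#' Cross-classifies the universe by query membership and set membership:
#' \code{OR = [a (N - K - k + a)] / [(k - a)(K - a)]} for observed overlap
#' a, query size k, set size K, universe size N. When any cell is zero,
#' 0.5 is added to every cell (Haldane-Anscombe) and the result is flagged.
#'
#' @param a Observed overlap.
#' @param k Query size.
#' @param K Set size.
#' @param N Universe size.
#' @return List: \code{or}, \code{continuity_corrected}.
#' @export
enrichment_odds_ratio <- function(a, k, K, N) {
  if (a > min(k, K) || k > N || K > N || a < 0 || N - K - k + a < 0)
    stop("impossible 2x2 table")
  cells <- c(a, k - a, K - a, N - K - k + a)
  cc <- any(cells == 0)
  if (cc) cells <- cells + 0.5
  list(or = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       continuity_corrected = cc)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (\code{min(1, m p)}) for the fixed tissue panels, or
#' Benjamini-Hochberg step-up for the open-ended term databases.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @param m Number of tests (>= length of \code{pvalues}; defaults to the
#'   length).
#' @return Adjusted p-value vector.
#' @export
adjust_pvalues <- function(pvalues, method = c("bonferroni", "bh"),
                           m = length(pvalues)) {
  method <- match.arg(method)
  if (m < length(pvalues)) stop("m must be >= number of p-values")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else
    "bonferroni", n = m)
}
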