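#' Construct a genotype container
#'
#' Holds a samples x variants dosage matrix together with per-variant minor
#' allele statistics. Dosages are alternate-allele counts in \{0, 1, 2\} (or
#' \code{NA}); on construction every variant is oriented to its minor allele
#' (dosage flipped to \code{2 - d} when the alternate allele frequency
#' exceeds 0.5), so downstream code can assume MAF in [0, 0.5].
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns, with
#'   dimnames. Entries in \{0, 1, 2\} or \code{NA}.
#' @param variants Optional data.frame with columns \code{id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}; defaults are invented
#'   from column names.
#' @return Object of class \code{GenotypeData}: \code{$dosages} (oriented),
#'   \code{$variants}, \code{$maf}, \code{$mac}, \code{$flipped} (logical,
#'   which variants were re-oriented).
#' @export
genotype_data <- function(dosages, variants = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("var", seq_len(ncol(dosages)))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (any(!dosages %in% c(0, 1, 2, NA)))
    stop("dosages must be in {0, 1, 2} or NA")
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(dosages),
                           chrom = "1", pos = seq_len(ncol(dosages)),
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  maf <- numeric(ncol(dosages)); mac <- integer(ncol(dosages))
  flipped <- logical(ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    st <- allele_stats(dosages[, j])
    maf[j] <- st$maf; mac[j] <- st$mac; flipped[j] <- st$flipped
    if (st$flipped) dosages[, j] <- 2 - dosages[, j]
  }
  names(maf) <- names(mac) <- colnames(dosages)
  structure(list(dosages = dosages, variants = variants,
                 maf = maf, mac = mac, flipped = flipped),
            class = "GenotypeData")
}

#' @export
print.GenotypeData <- function(x, ...) {
  cat(sprintf("GenotypeData: %d samples x %d variants (MAF %.2g-%.2g)\n",
              nrow(x$dosages), ncol(x$dosages),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' Minor allele frequency and count for one variant
#'
#' If the alternate allele frequency exceeds 0.5 the dosages are flipped to
#' \code{2 - d} before counting, so the returned statistics always describe
#' the minor allele. The denominator counts observed samples only.
#'
#' @param dosages Numeric vector of dosages in \{0, 1, 2\} or \code{NA}.
#' @return List with \code{maf}, \code{mac}, \code{n_obs}, \code{flipped}.
#' @export
allele_stats <- function(dosages) {
  obs <- !is.na(dosages)
  n <- sum(obs)
  if (n == 0) stop("all dosages missing")
  af <- sum(dosages[obs]) / (2 * n)
  flipped <- af > 0.5
  d <- if (flipped) 2 - dosages[obs] else dosages[obs]
  mac <- sum(d)
  list(maf = mac / (2 * n), mac = mac, n_obs = n, flipped = flipped)
}

#' Select qualifying variants per gene
#'
#' A variant qualifies for a gene when its in-sample minor allele frequency
#' is strictly below \code{maf_max} and its annotated consequence is in
#' \code{classes}. Variants annotated to several genes qualify for each
#' independently.
#'
#' @param geno A \code{GenotypeData}.
#' @param annotations data.frame with columns \code{variant_id}, \code{gene},
#'   \code{consequence}.
#' @param maf_max MAF upper bound (strict).
#' @param classes Consequence classes counted as potentially damaging.
#' @return Named list: per gene, the character vector of qualifying variant
#'   ids.
#' @export
qualify_variants <- function(geno, annotations, maf_max = 0.01,
                             classes = c("nonsynonymous", "stop gain",
                                         "stop loss", "splicing")) {
  stopifnot(all(c("variant_id", "gene", "consequence") %in% names(annotations)))
  known <- annotations$variant_id %in% colnames(geno$dosages)
  if (!all(known))
    stop("annotations reference unknown variants: ",
         paste(utils::head(annotations$variant_id[!known], 3), collapse = ", "))
  ok <- annotations$consequence %in% classes &
    geno$maf[annotations$variant_id] < maf_max
  ann <- annotations[ok, , drop = FALSE]
  split(ann$variant_id, ann$gene)
}

#' Group qualifying variants into testable gene units
#'
#' Genes are retained when they carry at least \code{min_variants}
#' qualifying variants and the summed minor allele count reaches
#' \code{min_mac}; gene groups below either bound are too sparse for stable
#' aggregation tests.
#'
#' @param geno A \code{GenotypeData}.
#' @param qualifying Named list of qualifying variant ids per gene, as
#'   returned by \code{\link{qualify_variants}}.
#' @param min_mac Minimum total minor allele count (inclusive).
#' @param min_variants Minimum number of contributing variants (inclusive).
#' @return List of \code{GeneGroup} objects (gene, variant ids, total MAC,
#'   cumulative MAF).
#' @export
build_gene_groups <- function(geno, qualifying, min_mac = 10,
                              min_variants = 2) {
  out <- list()
  for (g in names(qualifying)) {
    vs <- qualifying[[g]]
    if (length(vs) < min_variants) next
    total_mac <- sum(geno$mac[vs])
    if (total_mac < min_mac) next
    out[[g]] <- structure(list(gene = g, variant_ids = vs,
                               n_variants = length(vs),
                               total_mac = total_mac,
                               cumulative_maf = sum(geno$maf[vs])),
                          class = "GeneGroup")
  }
  out
}

#' @export
print.GeneGroup <- function(x, ...) {
  cat(sprintf("GeneGroup %s: %d variants, MAC %d, cumulative MAF %.3g\n",
              x$gene, x$n_variants, x$total_mac, x$cumulative_maf))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Missing dosages are replaced by the variant's observed mean dosage; this
#' keeps the sample size constant across variants and is the usual choice
#' for score-type tests. Observed values are unchanged and each variant's
#' mean is preserved exactly.
#'
#' @param dosages Numeric matrix (samples x variants).
#' @return Matrix without missing values.
#' @export
mean_impute <- function(dosages) {
  dosages <- as.matrix(dosages)
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (all(miss)) stop("variant with no observed dosage: column ", j)
    if (any(miss)) dosages[miss, j] <- mean(dosages[!miss, j])
  }
  dosages
}

#' Classify samples by qualifying-variant carrier status
#'
#' Per sample and gene group: \code{homozygous} if any member dosage is 2;
#' else \code{het-multiple} if two or more member dosages are 1; else
#' \code{het-single} if exactly one; else \code{non-carrier}. Missing
#' dosages count as non-carrying for classification.
#'
#' @param geno A \code{GenotypeData}.
#' @param group A \code{GeneGroup}.
#' @return List: \code{status} (factor per sample), \code{n_carriers}
#'   (samples with at least one qualifying allele), \code{carrier_fraction}.
#' @export
carrier_status <- function(geno, group) {
  G <- geno$dosages[, group$variant_ids, drop = FALSE]
  n_hom <- rowSums(G == 2, na.rm = TRUE)
  n_het <- rowSums(G == 1, na.rm = TRUE)
  status <- ifelse(n_hom >= 1, "homozygous",
            ifelse(n_het >= 2, "het-multiple",
            ifelse(n_het == 1, "het-single", "non-carrier")))
  status <- factor(status, levels = c("non-carrier", "het-single",
                                      "het-multiple", "homozygous"))
  carriers <- sum(status != "non-carrier")
  list(status = stats::setNames(status, rownames(G)),
       n_carriers = carriers,
       carrier_fraction = carriers / nrow(G))
}

#' Fraction of samples carrying a qualifying allele in any of several genes
#'
#' @param geno A \code{GenotypeData}.
#' @param groups List of \code{GeneGroup} objects.
#' @return List with \code{n_carriers}, \code{n_samples},
#'   \code{carrier_percent} (rounded to integer percent).
#' @export
overall_carrier_rate <- function(geno, groups) {
  vs <- unique(unlist(lapply(groups, `[[`, "variant_ids")))
  G <- geno$dosages[, vs, drop = FALSE]
  carrier <- rowSums(G >= 1, na.rm = TRUE) >= 1
  list(n_carriers = sum(carrier), n_samples = nrow(G),
       carrier_percent = round(100 * sum(carrier) / nrow(G)))
}
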