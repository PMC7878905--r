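#' Write a metabolite matrix as TSV
#'
#' Samples as rows, first column \code{sample_id}, one column per
#' metabolite; missing values as empty cells. Round-trips losslessly with
#' \code{\link{read_metabolite_tsv}}.
#'
#' @param m A \code{MetaboliteMatrix}.
#' @param path Output path.
#' @export
write_metabolite_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metabolite matrix from TSV
#'
#' @param path Input path.
#' @param pathway Optional named pathway vector.
#' @param state State flag to stamp on the result (default \code{"raw"}).
#' @return A \code{MetaboliteMatrix}.
#' @export
read_metabolite_tsv <- function(path, pathway = NULL, state = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  metabolite_matrix(v, pathway, state = state)
}

#' Write a dosage matrix as TSV
#'
#' @param geno A \code{GenotypeData} (or plain dosage matrix).
#' @param path Output path.
#' @export
write_dosage_tsv <- function(geno, path) {
  v <- if (inherits(geno, "GenotypeData")) geno$dosages else as.matrix(geno)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' @param path Input path.
#' @return A \code{GenotypeData}.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  genotype_data(v)
}

#' Write genotypes as a minimal VCF (v4.2, GT only)
#'
#' Biallelic SNVs, 1-based positions, genotypes coded \code{0/0},
#' \code{0/1}, \code{1/1}, missing \code{./.}. Dosages are written as
#' alternate-allele counts using the variant table's ref/alt.
#'
#' @param geno A \code{GenotypeData}.
#' @param path Output path.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(geno$dosages)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$dosages))) {
    d <- geno$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    v <- geno$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the GT field of a biallelic-SNV VCF into alternate-allele
#' dosages; \code{./.} becomes missing. Multiallelic records (comma in
#' ALT) are rejected with an error.
#'
#' @param path VCF path.
#' @return A \code{GenotypeData} (minor-allele oriented on construction).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multiallelic records are not supported; split them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  dos <- apply(gt, c(1, 2), count_alt)
  variants <- data.frame(id = rownames(gt),
                         chrom = vcfR::getCHROM(v),
                         pos = vcfR::getPOS(v),
                         ref = vcfR::getREF(v), alt = alt,
                         stringsAsFactors = FALSE)
  genotype_data(t(dos), variants)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then gene ids,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t")[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a covariate or annotation table as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
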