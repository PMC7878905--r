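#' Pipeline configuration
#'
#' Bundles the analysis thresholds and the simulation (or input) settings
#' for a reproducible end-to-end run. Thresholds default to the study's
#' choices: qualifying MAF < 1%, gene groups with >= 2 variants and
#' MAC >= 10, phenotypes observed in >= 300 samples, overall alpha 0.05
#' split over genes x phenotypes x 2 tests.
#'
#' @param simulation A \code{SimulationConfig} describing the synthetic
#'   cohort (or \code{NULL} when supplying data directly to the stage
#'   functions).
#' @param alpha Overall type-I error.
#' @param maf_max Qualifying-variant MAF bound (strict).
#' @param min_mac,min_variants Gene-group filters.
#' @param min_observations Minimum per-phenotype observation count.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param seed Root seed (defaults to the simulation config's seed).
#' @return A \code{RunConfig} list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            alpha = 0.05, maf_max = 0.01, min_mac = 10,
                            min_variants = 2, min_observations = 300,
                            out_dir = NULL, seed = NULL) {
  if (is.null(seed)) seed <- simulation$seed
  structure(list(simulation = simulation, alpha = alpha,
                 maf_max = maf_max, min_mac = min_mac,
                 min_variants = min_variants,
                 min_observations = min_observations,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

.covariate_design <- function(covariates) {
  as.matrix(data.frame(age = covariates$age, sex = covariates$sex,
                       egfr = covariates$egfr,
                       log_uacr = log(covariates$uacr),
                       pc1 = covariates$pc1, pc2 = covariates$pc2,
                       pc3 = covariates$pc3))
}

#' Simulate the cohort inputs for a run
#'
#' @param config A \code{RunConfig}.
#' @return List: covariates, genotypes/annotations (from
#'   \code{\link{simulate_genotypes}}), metabolites and truth (from
#'   \code{\link{simulate_metabolites}}).
#' @export
simulate_stage <- function(config) {
  sc <- config$simulation
  covariates <- simulate_covariates(sc$n_samples, seed = sc$seed + 1L)
  geno <- simulate_genotypes(sc)
  met <- simulate_metabolites(geno, covariates, sc)
  list(covariates = covariates, genotypes = geno$genotypes,
       annotations = geno$annotations,
       qualifying_counts = geno$qualifying_counts,
       metabolites = met$metabolites, truth = met$truth)
}

#' Metabolite preprocessing stage
#'
#' Outlier masking, probabilistic quotient normalization, the minimum
#' observation filter, and the inverse normal transform, in that order.
#'
#' @param metabolites Raw \code{MetaboliteMatrix}.
#' @param config A \code{RunConfig}.
#' @return List: \code{transformed} (INT \code{MetaboliteMatrix}) and
#'   \code{normalized} (the pre-INT, PQN state used for ratios).
#' @export
preprocess_stage <- function(metabolites, config) {
  masked <- mask_outliers(metabolites)
  normalized <- pqn_normalize(masked)
  normalized <- filter_min_observations(normalized,
                                        config$min_observations)
  list(transformed = int_transform(normalized), normalized = normalized)
}

#' Association stage: all gene groups against all phenotypes
#'
#' @param transformed INT \code{MetaboliteMatrix}.
#' @param covariates Covariate data.frame.
#' @param genotypes A \code{GenotypeData}.
#' @param annotations Variant annotation data.frame.
#' @param config A \code{RunConfig}.
#' @return List: \code{results} data.frame (one row per gene x phenotype)
#'   and \code{groups}.
#' @export
associate_stage <- function(transformed, covariates, genotypes,
                            annotations, config) {
  required <- c("age", "sex", "egfr", "uacr", "pc1", "pc2", "pc3")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols))
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  qual <- qualify_variants(genotypes, annotations,
                           maf_max = config$maf_max)
  groups <- build_gene_groups(genotypes, qual, min_mac = config$min_mac,
                              min_variants = config$min_variants)
  X <- .covariate_design(covariates)
  rows <- list()
  for (grp in groups) {
    for (ph in colnames(transformed$values)) {
      rows[[paste(grp$gene, ph)]] <-
        gene_test(transformed$values[, ph], X, genotypes, grp,
                  phenotype_id = ph)
    }
  }
  results <- if (length(rows)) do.call(rbind, c(unname(rows),
                                                list(make.row.names = FALSE)))
  else data.frame(gene = character(0), phenotype = character(0),
                  p_burden = numeric(0), effect = numeric(0),
                  se = numeric(0), p_skat = numeric(0),
                  n_snps = integer(0), total_mac = integer(0),
                  cumulative_maf = numeric(0), n = integer(0),
                  skat_p_method = character(0))
  list(results = results, groups = groups)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulation, preprocessing, qualifying-variant grouping, burden and SKAT
#' tests per gene and phenotype, and threshold-based result assembly, in
#' order. Re-running with an identical config reproduces the outputs
#' bit-identically. When \code{config$out_dir} is set, the results table,
#' significant/suggestive tables, and a JSON run summary (seed, thresholds,
#' counts) are written there.
#'
#' @param config A \code{RunConfig}.
#' @return List: \code{data} (simulated inputs), \code{results},
#'   \code{significant}, \code{suggestive}, \code{thresholds},
#'   \code{carriers}, \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  data <- simulate_stage(config)
  prep <- preprocess_stage(data$metabolites, config)
  assoc <- associate_stage(prep$transformed, data$covariates,
                           data$genotypes, data$annotations, config)
  n_genes <- max(length(assoc$groups), 1L)
  n_phen <- max(ncol(prep$transformed$values), 1L)
  th <- bonferroni_threshold(config$alpha, n_genes, n_phen, 2)
  th_sugg <- bonferroni_threshold(config$alpha, n_genes, 1, 2)
  assembled <- assemble_results(assoc$results, th$threshold,
                                th_sugg$threshold)
  carriers <- if (length(assoc$groups))
    overall_carrier_rate(data$genotypes, assoc$groups) else NULL
  out <- list(data = data, results = assoc$results,
              significant = assembled$significant,
              suggestive = assembled$suggestive,
              thresholds = list(significant = th$threshold,
                                suggestive = th_sugg$threshold,
                                n_genes = n_genes,
                                n_phenotypes = n_phen),
              carriers = carriers, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_tsv(assoc$results,
                    file.path(config$out_dir, "results.tsv"))
    write_table_tsv(assembled$significant,
                    file.path(config$out_dir, "significant.tsv"))
    write_table_tsv(assembled$suggestive,
                    file.path(config$out_dir, "suggestive.tsv"))
    jsonlite::write_json(
      list(seed = config$seed,
           thresholds = out$thresholds,
           n_results = nrow(assoc$results),
           n_significant = nrow(assembled$significant),
           carrier_percent = if (is.null(carriers)) NULL else
             carriers$carrier_percent),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
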