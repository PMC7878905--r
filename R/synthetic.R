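#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a CKD cohort of
#' 4864 participants genotyped for rare exonic variants, with urine
#' metabolite intensities confounded by per-sample dilution. Per-allele
#' effects of configured genes act additively on the inverse-normal
#' (latent) scale, in SD units, matching the scale on which the
#' association tests report effects (typical detected effects span roughly
#' 0.4-1.6 SD per allele).
#'
#' @param n_samples Cohort size (default 4864).
#' @param genes List of gene configurations, each a list with \code{gene}
#'   (id), \code{n_variants} (qualifying variants), \code{beta} (per-allele
#'   effect, SD units), and optionally \code{consequence_mix} (named
#'   probabilities over consequence classes).
#' @param maf_range Interval in (0, 0.01) from which qualifying-variant
#'   MAFs are drawn.
#' @param background_common_variants Number of common variants (MAF
#'   0.05-0.5) added as non-qualifying background.
#' @param dilution_sd Log-scale SD of the per-sample urine dilution factor.
#' @param missing_rate Probability a metabolite measurement is missing.
#' @param missing_mode \code{"mcar"} (completely at random) or
#'   \code{"censor"} (left-censoring: the lowest raw values go missing).
#' @param dosage_missing_rate Probability a dosage is missing (exercises
#'   imputation).
#' @param n_null_metabolites Extra metabolites with no genetic effect.
#' @param seed Root seed; child streams are derived per component as
#'   seed + 1 (covariates), + 2 (genotypes), + 3 (metabolites).
#' @return A validated \code{SimulationConfig} list.
#' @export
simulation_config <- function(n_samples = 4864,
                              genes = list(list(gene = "GENE1",
                                                n_variants = 6,
                                                beta = 0.7)),
                              maf_range = c(1e-4, 9e-3),
                              background_common_variants = 10,
                              dilution_sd = 0.5,
                              missing_rate = 0.05,
                              missing_mode = c("mcar", "censor"),
                              dosage_missing_rate = 0.002,
                              n_null_metabolites = 2,
                              seed = 1) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_samples >= 1,
            maf_range[1] > 0, maf_range[2] < 0.01,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate <= 1,
            dosage_missing_rate >= 0, dosage_missing_rate <= 1,
            dilution_sd >= 0)
  for (g in genes) {
    stopifnot(!is.null(g$gene), g$n_variants >= 1, is.finite(g$beta))
  }
  structure(list(n_samples = n_samples, genes = genes,
                 maf_range = maf_range,
                 background_common_variants = background_common_variants,
                 dilution_sd = dilution_sd, missing_rate = missing_rate,
                 missing_mode = missing_mode,
                 dosage_missing_rate = dosage_missing_rate,
                 n_null_metabolites = n_null_metabolites,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate cohort covariates
#'
#' Emulates the CKD cohort's marginal summaries: mean age 60 years (range
#' clipped to the 18-74 enrollment window), 60% men, mean eGFR
#' 49.5 ml/min/1.73m2, median UACR ~50 mg/g (log-normal), and three
#' standard-normal genetic principal components.
#'
#' @param n_samples Number of participants (>= 1).
#' @param seed Integer seed.
#' @return data.frame: sample_id, age, sex (1 = male), egfr, uacr,
#'   pc1, pc2, pc3.
#' @export
simulate_covariates <- function(n_samples, seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  age <- pmin(pmax(round(stats::rnorm(n_samples, 60, 10)), 18), 74)
  sex <- stats::rbinom(n_samples, 1, 0.6)
  egfr <- pmax(stats::rnorm(n_samples, 49.5, 15), 8)
  uacr <- stats::rlnorm(n_samples, meanlog = log(50.1), sdlog = 1.6)
  data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
             age = age, sex = sex, egfr = egfr, uacr = uacr,
             pc1 = stats::rnorm(n_samples), pc2 = stats::rnorm(n_samples),
             pc3 = stats::rnorm(n_samples), stringsAsFactors = FALSE)
}

.consequence_classes <- c("nonsynonymous", "stop gain", "stop loss",
                          "splicing", "synonymous")
.default_mix <- c(nonsynonymous = 0.7, `stop gain` = 0.1,
                  `stop loss` = 0.05, splicing = 0.15)

#' Simulate rare-variant genotypes with annotation
#'
#' Each configured gene receives its configured number of qualifying
#' variants: dosages are binomial(2, MAF) draws with MAF from
#' \code{maf_range}, resampled until the realized in-sample MAF is below
#' 0.01 with at least one carrier, so qualifying variants exist by
#' construction. Consequence labels are drawn from the gene's consequence
#' mix (default mostly nonsynonymous with stop/splice admixture).
#' Background common variants (MAF 0.05-0.5, labeled synonymous) are
#' appended under dummy gene ids. A small fraction of dosages is set
#' missing to exercise imputation.
#'
#' @param config A \code{SimulationConfig}.
#' @return List: \code{genotypes} (a \code{GenotypeData}),
#'   \code{annotations} (variant_id, gene, consequence),
#'   \code{qualifying_counts} (samples x genes matrix of true qualifying
#'   allele counts, before dosage masking).
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_samples
  if (1 / (2 * n) >= 0.01)
    stop("infeasible config: with n = ", n,
         " no non-zero MAF can stay below 0.01")
  set.seed(config$seed + 2L)
  dos <- list(); ann <- list(); qual_counts <- list()
  for (g in config$genes) {
    mix <- if (!is.null(g$consequence_mix)) g$consequence_mix else
      .default_mix
    gm <- matrix(0L, n, g$n_variants)
    for (j in seq_len(g$n_variants)) {
      repeat {
        maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
        d <- stats::rbinom(n, 2, maf)
        mac <- sum(d)
        if (mac >= 1 && mac / (2 * n) < 0.01) break
      }
      gm[, j] <- d
    }
    vid <- sprintf("%s_v%d", g$gene, seq_len(g$n_variants))
    colnames(gm) <- vid
    dos[[g$gene]] <- gm
    ann[[g$gene]] <- data.frame(
      variant_id = vid, gene = g$gene,
      consequence = sample(names(mix), g$n_variants, replace = TRUE,
                           prob = mix),
      stringsAsFactors = FALSE)
    qual_counts[[g$gene]] <- rowSums(gm)
  }
  if (config$background_common_variants > 0) {
    nb <- config$background_common_variants
    bg <- sapply(seq_len(nb), function(j)
      stats::rbinom(n, 2, stats::runif(1, 0.05, 0.5)))
    colnames(bg) <- sprintf("bg_v%d", seq_len(nb))
    dos[["..bg"]] <- bg
    ann[["..bg"]] <- data.frame(variant_id = colnames(bg),
                                gene = sprintf("BG%d", seq_len(nb)),
                                consequence = "synonymous",
                                stringsAsFactors = FALSE)
  }
  dosages <- do.call(cbind, unname(dos))
  rownames(dosages) <- sprintf("S%04d", seq_len(n))
  complete <- dosages
  if (config$dosage_missing_rate > 0) {
    miss <- matrix(stats::runif(length(dosages)) <
                     config$dosage_missing_rate,
                   nrow(dosages), ncol(dosages))
    dosages[miss] <- NA
  }
  qc <- do.call(cbind, qual_counts)
  rownames(qc) <- rownames(dosages)
  list(genotypes = genotype_data(dosages),
       annotations = do.call(rbind, c(unname(ann),
                                      list(make.row.names = FALSE))),
       qualifying_counts = qc,
       complete_dosages = complete)
}

#' Simulate raw urine metabolite intensities
#'
#' The generative model mirrors the analysis model: a latent
#' (pre-dilution) level per sample and metabolite is built additively on
#' the inverse-normal scale as
#' \code{z = sum_g beta_g * (qualifying allele count in g) + covariate
#' terms + N(0, 1)}; raw intensities are \code{exp(z)} multiplied by a
#' per-sample log-normal dilution factor shared across metabolites, with
#' missingness applied last. One metabolite is generated per configured
#' gene (named \code{met_<gene>}) plus the configured number of null
#' metabolites; super-pathway labels cycle through amino acid / peptide /
#' lipid-fatty acid so ratio construction is exercised.
#'
#' @param sim Output of \code{\link{simulate_genotypes}}.
#' @param covariates Output of \code{\link{simulate_covariates}}.
#' @param config The \code{SimulationConfig}.
#' @return List: \code{metabolites} (raw \code{MetaboliteMatrix}),
#'   \code{truth} (per-gene beta, per-sample dilution, covariate
#'   coefficients, latent matrix).
#' @export
simulate_metabolites <- function(sim, covariates, config) {
  n <- config$n_samples
  if (nrow(covariates) != n || nrow(sim$qualifying_counts) != n)
    stop("sample sets do not align")
  set.seed(config$seed + 3L)
  gamma <- c(age = 0.005, sex = 0.10, egfr = -0.005,
             log_uacr = 0.05, pc1 = 0.02, pc2 = 0.02, pc3 = 0.02)
  covterm <- gamma["age"] * covariates$age + gamma["sex"] * covariates$sex +
    gamma["egfr"] * covariates$egfr +
    gamma["log_uacr"] * log(covariates$uacr) +
    gamma["pc1"] * covariates$pc1 + gamma["pc2"] * covariates$pc2 +
    gamma["pc3"] * covariates$pc3
  genes <- vapply(config$genes, `[[`, "", "gene")
  betas <- stats::setNames(vapply(config$genes, `[[`, 0, "beta"), genes)
  n_met <- length(genes) + config$n_null_metabolites
  met_ids <- c(paste0("met_", genes),
               if (config$n_null_metabolites > 0)
                 sprintf("met_null%d", seq_len(config$n_null_metabolites)))
  latent <- matrix(NA_real_, n, n_met,
                   dimnames = list(covariates$sample_id, met_ids))
  for (i in seq_along(genes)) {
    latent[, i] <- betas[i] * sim$qualifying_counts[, genes[i]] +
      covterm + stats::rnorm(n)
  }
  if (config$n_null_metabolites > 0)
    for (i in seq_len(config$n_null_metabolites))
      latent[, length(genes) + i] <- covterm + stats::rnorm(n)
  dilution <- exp(stats::rnorm(n, 0, config$dilution_sd))
  raw <- exp(latent) * dilution
  if (config$missing_rate > 0) {
    # abundant endogenous metabolites (creatinine-like) are detected in
    # essentially every sample, and those near-complete metabolites form
    # the probabilistic-quotient reference; here the null metabolites
    # play that role, so the genetically driven metabolites never
    # contaminate the dilution reference in small panels
    complete_idx <- if (config$n_null_metabolites > 0)
      length(genes) + seq_len(config$n_null_metabolites)
    else seq_len(max(1L, ceiling(0.2 * n_met)))
    subject <- setdiff(seq_len(n_met), complete_idx)
    if (config$missing_mode == "mcar") {
      for (j in subject)
        raw[stats::runif(n) < config$missing_rate, j] <- NA
    } else {
      for (j in subject) {
        k <- floor(config$missing_rate * n)
        if (k > 0) raw[order(raw[, j])[seq_len(k)], j] <- NA
      }
    }
  }
  pathway <- rep(c("amino acid", "peptide", "lipid-fatty acid"),
                 length.out = n_met)
  names(pathway) <- met_ids
  list(metabolites = metabolite_matrix(raw, pathway, state = "raw"),
       truth = list(beta = betas, dilution = dilution, gamma = gamma,
                    latent = latent))
}

#' Simulate tissue-labeled expression data
#'
#' Baseline log-normal expression per gene; designated tissue-specific
#' genes have their mean multiplied by \code{fold} in their own tissue.
#' With a large fold the designated genes land in the top decile of the
#' per-tissue specificity t-statistics; with fold 1 the labels are
#' uninformative.
#'
#' @param n_genes Total genes.
#' @param tissues Character vector of tissue names (non-empty).
#' @param n_specific_per_tissue Designated specific genes per tissue.
#' @param fold Mean multiplier in the home tissue (>= 1).
#' @param seed Integer seed.
#' @param n_samples_per_tissue Samples per tissue (default 5).
#' @return List: \code{expression} (an \code{ExpressionData}),
#'   \code{truth} (named vector: designated gene -> home tissue).
#' @export
simulate_expression <- function(n_genes, tissues, n_specific_per_tissue,
                                fold, seed = 1, n_samples_per_tissue = 5) {
  if (length(tissues) == 0) stop("empty tissue list")
  if (n_specific_per_tissue * length(tissues) > n_genes)
    stop("more designated genes than genes")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  labels <- rep(tissues, each = n_samples_per_tissue)
  mu <- exp(stats::rnorm(n_genes, 1, 1))
  truth <- character(0)
  spec_gene_idx <- seq_len(n_specific_per_tissue * length(tissues))
  home <- rep(tissues, each = n_specific_per_tissue)
  x <- matrix(0, n_genes, length(labels),
              dimnames = list(genes, paste0("s", seq_along(labels))))
  for (j in seq_along(labels)) {
    m <- mu
    boosted <- spec_gene_idx[home == labels[j]]
    m[boosted] <- m[boosted] * fold
    x[, j] <- m * exp(stats::rnorm(n_genes, 0, 0.25))
  }
  truth <- stats::setNames(home, genes[spec_gene_idx])
  list(expression = expression_data(x, labels), truth = truth)
}

#' Analytic toy metabolic models for knockout direction calls
#'
#' Three linear-chain models with hand-computable optima covering the
#' three observed direction classes:
#' \describe{
#'   \item{degrader}{the enzyme consumes the metabolite (uptake bound 10,
#'     enzyme bound 8): healthy urine max 2, knockout 10 — KO raises urine
#'     excretion, the pattern of most detected genes.}
#'   \item{producer}{the enzyme makes the metabolite (uptake bound 10):
#'     healthy urine max 10, knockout 0 — KO lowers urine excretion.}
#'   \item{capacity_limited}{urine transport is capped at 1 independently
#'     of the enzyme: urine flux unchanged (1 vs 1) under KO while the
#'     blood demand flux rises (2 to 10).}
#' }
#'
#' @return Named list of three \code{MetabolicModel} objects; each carries
#'   the knockout gene id in its reactions' \code{genes} fields
#'   (\code{GENE_DEG}, \code{GENE_PROD}, \code{GENE_CAP}).
#' @export
toy_metabolic_models <- function() {
  degrader <- metabolic_model(
    "degrader",
    data.frame(id = c("A[c]", "B[c]", "A[u]"),
               compartment = c("c", "c", "u"), stringsAsFactors = FALSE),
    list(
      list(id = "R_uptake", metabolites = c(`A[c]` = 1), lb = 0, ub = 10,
           genes = character(0), organ = "gut"),
      list(id = "R_enzyme", metabolites = c(`A[c]` = -1, `B[c]` = 1),
           lb = 0, ub = 8, genes = "GENE_DEG", organ = "liver"),
      list(id = "R_sink_B", metabolites = c(`B[c]` = -1), lb = 0, ub = Inf,
           genes = character(0), organ = "liver"),
      list(id = "R_transport_u", metabolites = c(`A[c]` = -1, `A[u]` = 1),
           lb = 0, ub = Inf, genes = character(0), organ = "kidney"),
      list(id = "EX_A[u]", metabolites = c(`A[u]` = -1), lb = 0, ub = Inf,
           genes = character(0), organ = "kidney")))
  producer <- metabolic_model(
    "producer",
    data.frame(id = c("P[c]", "M[c]", "M[u]"),
               compartment = c("c", "c", "u"), stringsAsFactors = FALSE),
    list(
      list(id = "R_uptake", metabolites = c(`P[c]` = 1), lb = 0, ub = 10,
           genes = character(0), organ = "gut"),
      list(id = "R_enzyme", metabolites = c(`P[c]` = -1, `M[c]` = 1),
           lb = 0, ub = Inf, genes = "GENE_PROD", organ = "liver"),
      list(id = "R_transport_u", metabolites = c(`M[c]` = -1, `M[u]` = 1),
           lb = 0, ub = Inf, genes = character(0), organ = "kidney"),
      list(id = "EX_M[u]", metabolites = c(`M[u]` = -1), lb = 0, ub = Inf,
           genes = character(0), organ = "kidney")))
  capacity_limited <- metabolic_model(
    "capacity_limited",
    data.frame(id = c("M[c]", "X[c]", "M[u]", "M[bc]"),
               compartment = c("c", "c", "u", "bc"),
               stringsAsFactors = FALSE),
    list(
      list(id = "R_uptake", metabolites = c(`M[c]` = 1), lb = 0, ub = 10,
           genes = character(0), organ = "gut"),
      list(id = "R_enzyme", metabolites = c(`M[c]` = -1, `X[c]` = 1),
           lb = 0, ub = 8, genes = "GENE_CAP", organ = "liver"),
      list(id = "R_sink_X", metabolites = c(`X[c]` = -1), lb = 0, ub = Inf,
           genes = character(0), organ = "liver"),
      list(id = "R_transport_u", metabolites = c(`M[c]` = -1, `M[u]` = 1),
           lb = 0, ub = 1, genes = character(0), organ = "kidney"),
      list(id = "EX_M[u]", metabolites = c(`M[u]` = -1), lb = 0, ub = Inf,
           genes = character(0), organ = "kidney"),
      list(id = "R_transport_bc", metabolites = c(`M[c]` = -1,
                                                  `M[bc]` = 1),
           lb = 0, ub = Inf, genes = character(0), organ = "kidney"),
      list(id = "DM_M[bc]", metabolites = c(`M[bc]` = -1), lb = 0,
           ub = Inf, genes = character(0), organ = "blood")))
  list(degrader = degrader, producer = producer,
       capacity_limited = capacity_limited)
}
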