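#' Fit the covariate-only null model
#'
#' Least-squares regression of an inverse-normal transformed phenotype on
#' the covariates (age, sex, eGFR, UACR, principal components, and any
#' conditioning index-variant dosages). Rows with any missing value are
#' dropped (complete-case analysis; the retained sample ids are recorded).
#' The fitted object carries everything the score tests need: residuals,
#' the residual variance estimate RSS/(n - p), and the QR decomposition of
#' the design used to project genotypes off the covariate space.
#'
#' @param y Numeric response vector (may contain \code{NA}).
#' @param X Covariate matrix (without intercept; one is added), rows
#'   aligned with \code{y}. \code{NULL} for an intercept-only model.
#' @return Object of class \code{NullModel}: \code{y}, \code{X},
#'   \code{residuals}, \code{sigma2}, \code{n}, \code{p}, \code{qr},
#'   \code{kept} (row indices used).
#' @export
fit_null_model <- function(y, X = NULL) {
  y <- as.numeric(y)
  n_all <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n_all, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != n_all) stop("y and X have different numbers of rows")
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]
  Xf <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  n <- length(y); p <- ncol(Xf)
  if (n <= p) stop("fewer observations than parameters (n <= p)")
  qrx <- qr(Xf)
  if (qrx$rank < p) stop("singular design matrix (aliased covariates)")
  r <- qr.resid(qrx, y)
  sigma2 <- sum(r^2) / (n - p)
  structure(list(y = y, X = Xf, residuals = r, sigma2 = sigma2,
                 n = n, p = p, qr = qrx, kept = which(keep)),
            class = "NullModel")
}

#' @export
print.NullModel <- function(x, ...) {
  cat(sprintf("NullModel: n = %d, p = %d, sigma2 = %.4g\n",
              x$n, x$p, x$sigma2))
  invisible(x)
}

#' Variant weighting scheme for aggregation tests
#'
#' \code{"flat"} gives every variant weight 1, so the burden effect reads as
#' SD change per copy of a rare allele. \code{"beta"} weights each variant
#' by \code{dbeta(MAF, a, b)}; the default Beta(1, 25) up-weights the rarest
#' variants, the convention of the SKAT framework.
#'
#' @param name \code{"flat"} or \code{"beta"}.
#' @param a,b Beta density parameters (used when \code{name = "beta"}).
#' @return A \code{WeightScheme} object.
#' @export
weight_scheme <- function(name = c("flat", "beta"), a = 1, b = 25) {
  name <- match.arg(name)
  structure(list(name = name, a = a, b = b), class = "WeightScheme")
}

.variant_weights <- function(scheme, maf, m) {
  if (scheme$name == "flat") return(rep(1, m))
  if (is.null(maf)) stop("beta weights need per-variant MAF")
  w <- stats::dbeta(pmin(pmax(maf, 1e-12), 1 - 1e-12), scheme$a, scheme$b)
  if (any(w <= 0)) stop("non-positive weight")
  w
}

#' Gene-based burden test
#'
#' Collapses the (mean-imputed, minor-oriented) dosages of a gene's
#' qualifying variants into one weighted score per sample,
#' \code{s_i = sum_j w_j g_ij}, and tests its association with the
#' phenotype adjusted for the null-model covariates. With flat weights the
#' effect estimate is the average phenotype change in SD units per copy of
#' a qualifying rare allele. Writing P for the projection off the covariate
#' space, \code{beta = (s'r) / (s'Ps)}, \code{SE = sigma / sqrt(s'Ps)}, and
#' the two-sided p-value uses the standard normal reference (the large-n
#' convention of score tests).
#'
#' @param null A \code{NullModel}.
#' @param G Dosage matrix for the group's variants (samples x variants),
#'   mean-imputed, rows aligned with the null model's original input (rows
#'   dropped there are dropped here too).
#' @param weights A \code{WeightScheme}; default flat.
#' @param maf Optional per-variant MAF for beta weights; defaults to
#'   \code{colMeans(G) / 2}.
#' @return List: \code{beta}, \code{se}, \code{p}, \code{score_variance}
#'   (\code{s'Ps}).
#' @export
burden_test <- function(null, G, weights = weight_scheme("flat"),
                        maf = NULL) {
  G <- .align_geno(null, G)
  if (is.null(maf)) maf <- colMeans(G) / 2
  w <- .variant_weights(weights, maf, ncol(G))
  s <- as.vector(G %*% w)
  s_perp <- qr.resid(null$qr, s)
  sPs <- sum(s_perp^2)
  if (sPs < 1e-12) stop("burden score constant after covariate projection")
  beta <- sum(s_perp * null$residuals) / sPs
  se <- sqrt(null$sigma2 / sPs)
  z <- beta / se
  list(beta = beta, se = se,
       p = max(2 * stats::pnorm(-abs(z)), 1e-300),
       score_variance = sPs)
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test on the weighted genotype kernel:
#' \code{Q = || W G' r ||^2} with null distribution a mixture
#' \code{sum_k lambda_k chi-square(1)}, where the lambda are the
#' eigenvalues of \code{sigma2 * W G' P G W}. More powerful than the burden
#' test when variant effects differ in direction or many variants are
#' neutral. For a single variant SKAT reduces exactly to the squared-score
#' chi-square(1) test.
#'
#' @inheritParams burden_test
#' @param weights A \code{WeightScheme}; default Beta(1, 25) MAF weights.
#' @return List: \code{Q}, \code{p}, \code{lambdas}, \code{p_method}
#'   (\code{"imhof"} or \code{"liu"} when the integration fell back to
#'   moment matching).
#' @export
skat_test <- function(null, G, weights = weight_scheme("beta"),
                      maf = NULL) {
  G <- .align_geno(null, G)
  if (is.null(maf)) maf <- colMeans(G) / 2
  w <- .variant_weights(weights, maf, ncol(G))
  u <- as.vector(crossprod(G, null$residuals)) * w
  Q <- sum(u^2)
  Gp <- qr.resid(null$qr, G)
  A <- null$sigma2 * (crossprod(Gp) * tcrossprod(w))
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  if (length(lam) == 0) stop("all kernel eigenvalues are numerically zero")
  p <- quadform_pvalue(Q, lam)
  list(Q = Q, p = as.numeric(p), lambdas = lam,
       p_method = attr(p, "method"))
}

.align_geno <- function(null, G) {
  G <- as.matrix(G)
  if (nrow(G) != length(null$kept)) {
    G <- G[null$kept, , drop = FALSE]
  }
  if (anyNA(G)) stop("G must be mean-imputed (no missing dosages)")
  G
}

#' Upper-tail probability of a mixture of chi-square(1) variables
#'
#' Computes \code{P(sum_k lambda_k chi2_1 > q)} by numerical inversion of
#' the characteristic function (Imhof's integral), the machinery behind
#' SKAT p-values. Integration targets absolute accuracy 1e-9; if it fails
#' or returns an invalid probability, a skewness/kurtosis moment-matching
#' approximation (Liu) is used instead and flagged via the
#' \code{"method"} attribute.
#'
#' @param q Non-negative quadratic-form value.
#' @param lambdas Positive eigenvalue vector.
#' @param acc Absolute accuracy target for the integration.
#' @return Upper-tail probability in (0, 1], with attribute \code{"method"}.
#' @export
quadform_pvalue <- function(q, lambdas, acc = 1e-9) {
  if (!is.finite(q) || any(!is.finite(lambdas))) stop("non-finite input")
  if (q < 0) stop("q must be non-negative")
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0) stop("need at least one positive eigenvalue")
  m <- length(lambdas)
  # equal eigenvalues: the mixture is an exactly scaled chi-square
  if (diff(range(lambdas)) <= 1e-12 * max(lambdas)) {
    p <- stats::pchisq(q / max(lambdas), df = m, lower.tail = FALSE)
    p <- min(max(p, 1e-300), 1)
    attr(p, "method") <- "exact"
    return(p)
  }
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambdas^2, u^2))))
    ifelse(u == 0, 0.5 * (sum(lambdas) - q), sin(theta) / (u * rho))
  }
  p <- NA_real_
  method <- "imhof"
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, abs.tol = acc, rel.tol = acc,
                     subdivisions = 10000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (!is.null(res) && res$message %in% c("OK", "roundoff error was detected"))
    p <- 0.5 + res$value / pi
  # tails below the integration's absolute resolution, or failed inversions,
  # go through the moment-matching approximation (flagged, never silent)
  if (is.na(p) || p < 10 * acc || p > 1 + 1e-6) {
    p <- .liu_pvalue(q, lambdas)
    method <- "liu"
  }
  p <- min(max(p, 1e-300), 1)
  attr(p, "method") <- method
  p
}

# Liu et al. moment-matching approximation: match skewness (or kurtosis when
# infeasible) of the mixture with a noncentral chi-square.
.liu_pvalue <- function(q, lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
    a <- sqrt(df)
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  q_new <- t_star * sqrt(2) * a + df + delta
  stats::pchisq(q_new, df = df, ncp = delta, lower.tail = FALSE)
}

#' Single-variant score tests
#'
#' Covariate-adjusted linear-regression slope and two-sided p-value for each
#' variant separately; the per-variant analogue of the burden test (a
#' single flat-weighted variant gives identical output).
#'
#' @inheritParams burden_test
#' @return data.frame with one row per variant: \code{variant_id},
#'   \code{beta}, \code{se}, \code{p}.
#' @export
single_variant_tests <- function(null, G) {
  G <- .align_geno(null, G)
  if (is.null(colnames(G)))
    colnames(G) <- paste0("var", seq_len(ncol(G)))
  out <- data.frame(variant_id = colnames(G), beta = NA_real_,
                    se = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(G))) {
    fit <- burden_test(null, G[, j, drop = FALSE])
    out$beta[j] <- fit$beta; out$se[j] <- fit$se; out$p[j] <- fit$p
  }
  out
}

#' Re-test a gene conditional on common index variants
#'
#' Adds the dosage(s) of nearby common GWAS index variant(s) to the
#' covariates and recomputes both aggregation tests. If the rare-variant
#' signal is driven by linkage with the common variant, the conditional
#' effect collapses toward zero; an independent signal keeps roughly 100%
#' of its unconditional effect.
#'
#' @param y Phenotype vector.
#' @param X Covariate matrix (no intercept), as for
#'   \code{\link{fit_null_model}}.
#' @param G Mean-imputed dosage matrix for the gene group.
#' @param index_dosages Vector or matrix of index-variant dosages aligned
#'   with \code{y}.
#' @param weights_burden,weights_skat Weight schemes for the two tests.
#' @param maf Optional per-variant MAF vector for SKAT weights.
#' @return List with \code{unconditional} and \code{conditional} (each
#'   containing \code{burden} and \code{skat} results) and
#'   \code{effect_proportion_pct}.
#' @export
conditional_reanalysis <- function(y, X, G, index_dosages,
                                   weights_burden = weight_scheme("flat"),
                                   weights_skat = weight_scheme("beta"),
                                   maf = NULL) {
  index_dosages <- as.matrix(index_dosages)
  if (nrow(index_dosages) != length(y))
    stop("index dosages do not align with samples")
  null0 <- fit_null_model(y, X)
  Xc <- cbind(X, index_dosages)
  null1 <- tryCatch(fit_null_model(y, Xc), error = function(e)
    stop("index SNP collinear with existing covariates: ",
         conditionMessage(e)))
  uncond <- list(burden = burden_test(null0, G, weights_burden, maf),
                 skat = skat_test(null0, G, weights_skat, maf))
  cond <- list(burden = burden_test(null1, G, weights_burden, maf),
               skat = skat_test(null1, G, weights_skat, maf))
  list(unconditional = uncond, conditional = cond,
       effect_proportion_pct = effect_proportion(cond$burden$beta,
                                                 uncond$burden$beta))
}

#' Conditional-to-unconditional effect proportion
#'
#' \code{round(100 * beta_cond / beta_uncond)} to the nearest integer
#' percent; near 100% the rare-variant association is independent of the
#' conditioning variant, near 0% it is abolished. A sign flip between the
#' two estimates triggers a warning (the percentage is then of doubtful
#' interpretation).
#'
#' @param beta_cond Conditional burden effect.
#' @param beta_uncond Unconditional burden effect (non-zero).
#' @return Integer percent.
#' @export
effect_proportion <- function(beta_cond, beta_uncond) {
  if (beta_uncond == 0) stop("unconditional effect is zero")
  if (sign(beta_cond) * sign(beta_uncond) < 0)
    warning("conditional and unconditional effects have opposite signs")
  as.integer(round(100 * beta_cond / beta_uncond))
}

#' Run burden and SKAT for one gene group against one phenotype
#'
#' Convenience wrapper producing one result record in the shape of the
#' main results table: both tests plus group bookkeeping.
#'
#' @param y Phenotype vector (INT scale).
#' @param X Covariate matrix (no intercept).
#' @param geno A \code{GenotypeData}.
#' @param group A \code{GeneGroup}.
#' @param phenotype_id Label stored in the record.
#' @return One-row data.frame: gene, phenotype, p_burden, effect, se,
#'   p_skat, n_snps, total_mac, cumulative_maf, n.
#' @export
gene_test <- function(y, X, geno, group, phenotype_id = "phenotype") {
  null <- fit_null_model(y, X)
  G <- mean_impute(geno$dosages[, group$variant_ids, drop = FALSE])
  maf <- geno$maf[group$variant_ids]
  b <- burden_test(null, G, weight_scheme("flat"))
  s <- skat_test(null, G, weight_scheme("beta"), maf = maf)
  data.frame(gene = group$gene, phenotype = phenotype_id,
             p_burden = b$p, effect = b$beta, se = b$se, p_skat = s$p,
             n_snps = group$n_variants, total_mac = group$total_mac,
             cumulative_maf = group$cumulative_maf, n = null$n,
             skat_p_method = s$p_method, stringsAsFactors = FALSE)
}
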