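---
title: "Methods: rare-variant association for urine metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant association for urine metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromet)
```

# Scope and model

`uromet` tests whether the aggregate of rare, putatively damaging exonic
variants in a gene shifts the urine concentration of a metabolite or of a
metabolite ratio. The analysis assumes unrelated individuals, a
quantitative phenotype made comparable across metabolites by a rank-based
inverse normal transform (INT), and additive per-allele effects. All
gene-level inference is score-type: the phenotype is regressed once on
covariates (age, sex, eGFR, log UACR, three genetic principal
components), and genotypes are only ever compared against the residuals
of that null fit. Mixed models are deliberately out of scope — with
unrelated participants and fixed covariates, ordinary least squares is
the appropriate null.

## Preprocessing

The metabolite matrix moves through four states in a fixed order, and
each operation refuses input in the wrong state:

1. **Outlier masking.** Per metabolite, values more than `k = 5` SD from
   the metabolite mean (moments computed in one pass over observed
   values, candidate included) are set to missing. The inequality is
   strict, so a value at exactly 5 SD stays. Zero-SD (constant) columns
   mask nothing. Masking precedes normalization so that a single
   aberrant measurement cannot corrupt the dilution quotients.
2. **Probabilistic quotient normalization.** Urine concentration varies
   strongly with hydration, multiplying every metabolite in a sample by
   a common dilution factor. The reference spectrum is the
   per-metabolite median over samples, restricted to metabolites with
   missing fraction < 1% (near-complete, abundant endogenous compounds);
   each sample is divided by the median ratio of its values to the
   reference. When data are exactly `profile × dilution`, the recovered
   quotients equal the dilution factors up to a global constant, and the
   normalized matrix is exact to numerical precision — a property the
   test suite checks at 1e-12.
3. **Observation filter.** Metabolites or ratios quantified in fewer
   than 300 samples are dropped (inclusive bound: 300 observations pass,
   299 do not); rank-based tests on sparser phenotypes are unstable.
4. **INT.** Observed values are replaced by
   `qnorm((rank − 0.5)/n_observed)`, ties averaged. The 0.5 offset is
   symmetric (transformed values of tie-free input sum to zero); other
   common offsets differ negligibly and none is canonical.

Ratios are built on the **normalized, pre-INT** scale, one per unordered
pair of eligible metabolites, numerator chosen lexicographically. INT is
rank-only, so ratios of INT values would be meaningless, while INT
applied *after* the ratio gives identical output whether one uses the
ratio or its log — which is why the pipeline does not need to take a
position on that choice. A ratio is missing wherever either member is
missing or the denominator is zero (missing, never an error: zero
intensities are data, not user mistakes).

## Gene-based tests

Qualifying variants have in-sample MAF strictly below 1% (the cohort is
the authority on its own allele frequencies, not a reference panel) and
a consequence in {nonsynonymous, stop gain, stop loss, splicing}. Genes
need at least 2 qualifying variants and a summed minor allele count of
at least 10. Missing dosages are mean-imputed per variant, which keeps
the sample constant across variants and is standard for score tests;
variants annotated to several genes count for each.

With null-model residuals `r`, residual variance `σ̂² = RSS/(n − p)`,
and projection `P` off the covariate space:

* **Burden**: `s = Gw`, `β̂ = sᵀr / sᵀPs`, `SE = σ̂/√(sᵀPs)`. Weights
  are flat (`w = 1`) so that `β̂` reads as SD change per copy of a rare
  allele — the scale on which effects are reported. The p-value uses
  the standard normal reference; at n ≈ 4,800 the difference from a t
  reference is far below reporting precision.
* **SKAT**: `Q = ‖W Gᵀr‖²` with Beta(1, 25) MAF weights, the
  established convention that up-weights the rarest variants. The null
  distribution is the eigenvalue mixture `Σ λₖ χ²₁` of
  `σ̂² · W Gᵀ P G W`.

The two tests are complementary: burden gains power when effects share a
direction, SKAT when they oppose or when many grouped variants are
neutral. The test suite verifies both claims by simulation, plus exact
reduction of both tests to the single-variant score test at m = 1.

## Mixture chi-square tails

`quadform_pvalue()` computes `P(Σ λₖ χ²₁ > q)` by Imhof's
characteristic-function inversion with an absolute accuracy target of
1e-9 (`stats::integrate`, up to 10,000 subdivisions). Two special paths:

* Equal eigenvalues are an exactly scaled chi-square and are computed in
  closed form (`method = "exact"`), which also covers every m = 1 call.
* When the integral fails or the p-value sits below the integration's
  absolute resolution (10× the accuracy target), a Liu-type
  skewness/kurtosis moment match is used instead and flagged
  (`method = "liu"`), never silently. Deep tails from numerical
  inversion at absolute tolerance are untrustworthy; the flagged
  approximation is the honest alternative.

All reported p-values are clamped into (0, 1e-300] ∪ … ∪ (0, 1] —
never exactly zero.

## Thresholds, p-gain, conditional analysis

The study-wide significance level divides α = 0.05 by genes ×
phenotypes × 2 tests, with the gene count recomputed from the data as
the number of groups passing filters. The suggestive level uses one
phenotype. The p-gain of a ratio, `min(p_A, p_B)/p_ratio`, is computed
in log10 space so that p-values at the double floor cannot overflow, and
ratio findings are retained only above 10 × (number of ratios). P-gains
are computed within each test (burden p-gain from burden p-values, SKAT
from SKAT), matching how they are tabulated.

Conditional analysis appends index-SNP dosages (one or several at once)
to the covariates and re-runs both tests; the effect proportion
`round(100·β̂_cond/β̂_uncond)` summarizes how much of the rare-variant
signal is independent of the common variant. An index SNP identical to
the burden score is degenerate (the projected score is constant) and is
reported as an error rather than a 0% — the test suite covers the
near-collinear case that motivates the statistic.

## Enrichment

Tissue- or cell-type-specific gene sets take the top
`ceiling(0.10 · G)` genes by the t-statistic of a focal-label indicator
in a linear model of `log10(x + 1)` expression — realized as the
pooled-variance two-group t, the special case that model reduces to with
no further covariates. The exact model behind such published lists is
rarely restated; this choice is documented as the package's own. Ties at
the decile boundary break by gene id for determinism.

Monte-Carlo enrichment draws uniform k-subsets of the universe without
replacement and uses the add-one estimator
`p = (1 + #{overlap ≥ observed}) / (1 + n_draws)`, which can never
return zero. Under uniform drawing it converges to the hypergeometric
upper tail; the suite checks agreement within 3 Monte-Carlo standard
errors at 1e5 draws over 20 random configurations. The default
`n_draws = 1e5` is a desk-scale compromise; production analyses raise it
(the construction is identical). Odds ratios come from the 2×2
membership table over the universe with Haldane–Anscombe 0.5-correction
on zero cells, flagged when applied. Bonferroni serves fixed tissue
panels, Benjamini–Hochberg the open-ended GO/KEGG term lists.

## Flux balance analysis knockouts

Models are linear programs: maximize one reaction's flux subject to
steady state `S·v = 0` and bounds. "Infinity" is an explicit bound of
1e6 with detection — an optimum within a factor 2 of the cap is reported
`unbounded`, never silently truncated. The LP core is a two-phase dense
tableau simplex with Bland's rule (no cycling); fixed variables are
substituted out and upper bounds become slack rows. At toy-model sizes
(≤ 10 reactions) this is exact to 1e-9, and the suite validates it
against brute-force vertex enumeration on random models.

A knockout zeroes the bounds of every reaction carrying the gene, in all
organ tags; genes sharing any reaction with an isozyme are refused,
since the surviving enzyme would mask the knockout. The healthy
reference maximizes the gene's reactions jointly (their summed flux) and
fixes each at that optimum; joint maximization cannot create
infeasibility between the gene's own reactions, which sequential
fixing can — a sequential mode exists behind a flag for comparison.
Direction calls compare knockout vs healthy maxima of the opened
`EX_<met>[u]` or `DM_<met>[bc]` reaction at relative tolerance 1e-6
(absolute floor 1e-9).

Three bundled toy models have hand-computable optima and realize the
three observed direction classes: a *degrader* (enzyme consumes the
metabolite; knockout raises urine flux 2 → 10), a *producer* (knockout
abolishes it, 10 → 0), and a *capacity-limited* exporter (urine
transport capped independently of the enzyme: urine 1 → 1 unchanged,
blood demand 2 → 10 up). Prediction–observation concordance uses the
exact one-sided binomial tail by direct summation; the chance model
(`null_p`) is an explicit argument, since a three-outcome direction call
admits several defensible nulls (1/3 under uniform chance, or the
empirical base rate), and the package does not guess between them.

# The synthetic cohort

The generator's defaults emulate the study conditions the pipeline is
designed for: 4,864 participants, mean age 60 (clipped to the 18–74
enrollment window), 60% male, mean eGFR 49.5 ml/min/1.73 m², log-normal
UACR with median ≈ 50 mg/g, and standard-normal principal components.
Qualifying variants are binomial(2, MAF) draws with MAF in a
configurable sub-1% range, resampled until the realized in-sample MAF is
below 1% with at least one carrier — the allele-frequency contract holds
by construction, not in expectation. Effects enter additively on the
latent inverse-normal scale in SD units (the scale on which results are
reported; detected effects in this setting typically span ~0.4–1.6 SD
per allele), raw intensities are `exp(latent) × dilution` with a
per-sample log-normal dilution factor (default log-SD 0.5, a realistic
spread for spot urine), and missingness is applied last.

Two missingness mechanisms are provided — missing-completely-at-random
(default) and left-censoring at the detection limit — because the true
mechanism in such cohorts is not documented; both are exercised in
tests and neither is asserted to be the real one. Null "endogenous
background" metabolites are kept fully observed and serve as the PQN
reference anchors: in real panels the quotient is computed over hundreds
of near-complete metabolites, so a genetically driven metabolite cannot
dominate it, and small simulated panels must preserve that property
(with ~5 metabolites, letting the causal column into a tiny reference
visibly leaks its signal into everything else — the package's test for
this failure mode exists because it happened).

Randomness derives from one root seed with fixed per-component offsets
(+1 covariates, +2 genotypes, +3 metabolites), so stages are
independently reproducible and identical seeds give bit-identical
output.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
(variants are independent), population stratification, batch or run-day
effects, covariate measurement error, informative missingness coupled to
genotype, and the correlation structure of real metabolite panels. The
synthetic validation shows the estimators are correct under the model's
own assumptions; it cannot show the assumptions hold in any cohort.

# Problem sizes and runtime choices

The test suite and acceptance script use sizes chosen to make
Monte-Carlo assertions sharp while staying desk-scale: type-I error
calibration uses 2,000 null phenotypes of n = 2,000 with one 6-variant
gene at MAF 0.005 (binomial SE ≈ 0.005 at α = 0.05, so the accepted band
0.040–0.060 is ±2 SE); effect recovery uses 200 replicates at n = 4,800
with total MAC ≈ 60 through the full PQN + INT path; enrichment
convergence uses 1e5 draws; the mixture-tail check uses 1e6 Monte-Carlo
draws. The mean recovered effect (≈ 0.68 for a true 0.7) reflects the
mild, expected attenuation of quotient noise plus INT rescaling at panel
size 25, not estimator bias; coverage stays at the nominal 95%.

# Known limitations

* Binary traits (logistic/mixed-model tests) are out of scope.
* The FBA module reads its own JSON schema, not SBML, and targets
  toy-scale models; whole-body reconstructions need a production LP
  solver.
* The enrichment module consumes expression matrices and gene sets; it
  does not build term databases.
* Threshold arithmetic reproduces printed study levels exactly, but
  cohort-level discovery results require the original restricted data
  and are not reproducible from synthetic cohorts by design.
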