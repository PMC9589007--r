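---
title: "Models and methods behind protflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

protflow implements the downstream statistical analysis of a multi-tissue
label-free proteomics study of type 2 diabetes: from per-tissue protein
intensity matrices with missing values to tables of differentially abundant
proteins and consensus-enriched gene sets. This vignette is the package's
account of the models it fits, the knobs that matter, and the choices made
where the design was genuinely open. Everything quantitative claimed here is
computed by the test suite or by `scripts/acceptance.R`; nothing is quoted
from external data.

## The data model

A tissue's measurements live in an `IntensityMatrix`: proteins x samples,
log2 scale, `NA` marking unquantified cells. The cohort has three glycemic
groups — normoglycemic controls (CTRL), prediabetes (PD) and type 2 diabetes
(T2D) — with 17/14/12 subjects by default, sampled in up to five tissues
(pancreatic islets, liver, skeletal muscle, visceral adipose tissue, serum).
Sample metadata carries the clinical and technical covariates that organ
donation introduces: BMI, age, cold ischemic time (CIT, hours), days in
intensive care, and the purity of the islet preparation (islet tissue only),
plus two traits used for correlation analyses, HbA1c (%) and
glucose-stimulated insulin secretion (GSIS).

## Quality control

**Sample outliers.** Each sample is scored by the deviation of its median
observed abundance from the tissue's cohort: `d_s = (median_s - M)/SD` with
`M` the median of per-sample medians. `SD` is estimated robustly as
`1.4826 * MAD`. This is a deliberate choice, not a convenience: a plain
standard deviation contains the outlier itself, and with `n` samples a lone
aberrant sample can reach at most about `(n - 1)/sqrt(n)` plain SDs — under
a 3-SD rule in a ~40-sample cohort it would largely mask itself. The MAD
scale reproduces the intent of "3 standard deviations from the overall
median" without the masking. A subject is recommended for exclusion only
when flagged in *every* tissue where it has a sample ("consistent"
deviation); a single-tissue fluctuation is not treated as a subject-level
problem.

**Presence filter.** A protein is kept when observed in at least 80% of a
tissue's samples (inclusive: 8 of 10 passes). The filter runs per tissue,
after outlier-sample removal, and is idempotent.

**Gene-level aggregation.** Proteins mapping to one gene are averaged
within samples over *observed* values only; a cell is missing only when all
contributing proteins are missing. Averaging before imputation must not
fabricate values, hence the missing-aware mean.

## Normalization and left-censored imputation

**Median sweep.** Each sample's observed values are shifted so all sample
medians equal the global target (the median of pre-normalization sample
medians). The operation is idempotent and equivariant under constant
shifts.

**QRILC.** Missingness in label-free proteomics concentrates below the
detection limit, so a missing-at-random imputer would be biased upward.
Per sample: with missing fraction `f`, the sorted observed values get Blom
plotting positions `p_i = f + (1 - f)(i - 0.375)/(m + 0.25)` — under left
censoring the observed values occupy the *upper* quantiles of the latent
distribution. A least-squares fit of observed values against `qnorm(p_i)`
gives the latent mean and SD (`mu`, `sigma`); missing cells are drawn from
`N(mu, tune_sigma * sigma)` truncated above at the fitted `f`-quantile
`Q = mu + sigma * qnorm(f)`, so imputations represent the censored lower
tail. `tune_sigma` defaults to 1. Imputation is per sample column — the
construction the published QRILC procedure uses; whether the original
analysis ran it per sample or per matrix is not stated, so the per-sample
convention is declared here, not inferred. A degenerate fit
(`sigma <= 1e-8`, e.g. a constant column) falls back to half-minimum
imputation with a warning; the tolerance exists because a constant column
yields a float-noise slope rather than an exact zero. On a 5000-value
column of `N(20, 2)` with the bottom 20% censored, the fit recovers `mu`
within 0.1 and `sigma` within a few percent (verified in the suite and
recomputed by the acceptance script).

## Identifier resolution

Gene-set collections (GMT files) are unioned into a universe of unique gene
names. Each quantified protein carries an ordered candidate-identifier list
(most confident first); the earliest candidate found in the universe is
used, otherwise the first candidate as-is. Matching is exact and
case-sensitive by default (GMT symbols are canonical); a case-folding
toggle exists but is off.

## Covariate selection and trait correlations

Candidate covariates are screened marginally: per protein, the R-squared of
a one-covariate least-squares fit (group-means model for categorical
covariates), summarized as the median across proteins. A covariate is
selected when that median reaches 1% in at least one tissue (inclusive);
islet purity is only eligible in the islet tissue. Marginal screening — not
joint variance partitioning — matches the screen-then-adjust design of the
analysis.

Trait correlations are Spearman on pairwise-complete cases with BH
q-values. Partial correlations take ranks first (consistency with the
Spearman choice), then remove covariates from both protein and trait by
least squares and correlate the residuals. The with/without-BMI comparison
at the `|0.4|` threshold classifies BMI-sensitive associations. One
caveat the tests document: when a protein is a nearly noise-free monotone
function of a covariate, the rank transform leaves a shared nonlinear
remainder that linear residualization cannot remove — partials are
interpretable for moderately noisy biology, not for deterministic
relations. Whether the original partials were Pearson or Spearman is
unstated; the rank-based choice here is declared.

## Differential abundance

For each tissue and contrast the design has an intercept, a B-vs-A group
indicator (pairwise contrasts among CTRL/PD/T2D plus the merged groups
CTRL+PD and PD+T2D), centered continuous covariates and categorical
dummies. Ordinary least squares runs per protein on the imputed (complete)
matrix; residual variances are then moderated by the closed-form
empirical-Bayes scheme: with `z = log(s^2)`, the prior degrees of freedom
`d0` solve `trigamma(d0/2) = var(z) - trigamma(d/2)` and the prior variance
`s0^2` follows from `mean(z)` via the matching digamma identity; the
posterior variance is `(d0 s0^2 + d s^2)/(d0 + d)` and the moderated t has
`d0 + d` degrees of freedom. When `var(z) <= trigamma(d/2)` there is no
excess dispersion, `d0` is infinite and every posterior variance equals
`s0^2`. The suite verifies this against an independent closed-form oracle
and against `limma::eBayes` to 1e-10. One boundary worth knowing: for a
*degenerate* constant-variance input the moment estimator maps `s^2` to
`s^2 * exp(log(d/2) - digamma(d/2))` (the digamma offset is exact for log
chi-square sampling, and the reference implementation behaves identically).

P-values are BH-adjusted to q-values (a Storey variant with fixed
`lambda = 0.5` is available); the ranking statistic is
`pi = logFC * (-log10 q)`, signed by the fold change, sorted descending
for enrichment.

## Dual enrichment and consensus

**Competitive parametric test.** For a set of size `m` among `G` ranked
statistics, a two-sample t on set-vs-rest means with the set variance
inflated by `VIF = 1 + (m - 1) rho`; `rho = 0.01` by default (the
conventional pre-ranked value, since statistics rather than expression are
supplied). At `rho = 0` it is exactly the pooled two-sample t-test.

**Permutation GSEA.** The weighted running sum (weight 1 on `|stat|`) gives
the enrichment score; significance comes from random same-size gene sets:
`p = (1 + #{same-sign perm ES beyond ES}) / (1 + #{same-sign perm ES})`,
`NES = ES / mean(|same-sign perm ES|)`. Null draws are shared across sets
of equal size. Default 10,000 permutations per size — the same estimator as
a million-permutation run with wider Monte-Carlo error; extreme p saturate
at `1/(n_perm + 1)`. Ties between the positive and negative maximum
deviation are exact events (both deviations can be integer multiples of the
miss step), so the tie comparison uses a 1e-10 tolerance and returns 0.

**Consensus.** Each method's p-values are FDR-adjusted within its own
family (per tissue, contrast and collection); a set is consensus-enriched
when both q-values are below 0.05 with the same direction. Sets outside
the 5–300 size band (after intersection with the ranked list) are excluded.

**Over-representation.** Tissue-specific and tissue-shared protein lists
are tested by the upper-tail hypergeometric against explicit backgrounds:
the tissue's own identifications for tissue-specific lists, the union
across tissues for shared lists.

**Enrichment map.** Consensus sets with both q-values below 0.01 become
nodes; edges join sets whose member overlap coefficient
`|A ∩ B| / min(|A|, |B|)` reaches 0.5. The published networks do not print
their similarity metric or cutoff; both are exposed in the configuration.

## The synthetic cohort generator

The generator exists so every stage can be tested against known truth. On
the log2 scale,

```
y[p, s] = mu_p + b[p, subject] + group_offset[p, group(s)]
          + sum_c slope_c (x_c - mean x_c) + N(0, residual_sd)
```

with `mu_p ~ U(16, 28)` (spanning a realistic label-free dynamic range so
the censoring curve is exercised), subject-level baselines
`b ~ N(0, 0.5)` shared across tissues (effects are tissue-specific, the
baselines are not — mirroring per-tissue analyses of the same donors), and
`residual_sd = 0.6`. Covariate distributions default to plausible clinical
values (BMI ~ N(26.5, 4), age ~ N(58, 11), CIT ~ N(11, 4) hours, ICU days
1 + Poisson(3), islet purity U(40, 90)%); HbA1c and GSIS are drawn per
group so the trait-group associations exist by construction. Missingness
follows a probit detection-limit model:
`P(missing | v) = pnorm((T_s - v)/kappa) + mcar`, with `T_s` the sample's
`censor_quantile` quantile (default 0.15) and `kappa = 0.3` log2 units;
`kappa -> 0` is a hard threshold. The real study does not report its
per-tissue missingness rates, so these defaults are free parameters of the
artifact, not estimates.

What the generator does *not* emulate: peptide-level structure, shared
peptides, acquisition batch effects, serum's dynamic-range compression, and
correlated protein modules outside the planted sets. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under its assumptions, not performance on real spectra-derived data.

## Calibration and recovery experiments

The suite and `scripts/acceptance.R` run three standing experiments
(problem sizes chosen as a practical desk scale):

- **Null calibration** — cohorts with no group effect, 2000 proteins, 500
  random sets: per-protein p-values are uniform (KS), the competitive
  test rejects at ~5%, and consensus false positives are absent (at most
  one per run). One subtlety: the 500 set tests within a run share one
  ranked vector and are correlated, so the rejection *rate* is estimated
  across several independent null cohorts before being compared to the
  binomial interval of a single 500-set experiment.
- **Recovery** — 17/14/12 cohort, 3000 proteins, five planted 20-gene sets
  with a 1-log2-unit T2D-vs-CTRL effect, 15% left-censored missingness,
  QRILC, dual enrichment: the median planted-set consensus count is 5/5
  and the median log-fold-change bias is well under 0.05. The power
  measurement uses the planted collection as its FDR family; specificity
  is what the null experiment measures. This split is deliberate: with
  few strongly affected genes the π landscape is spiky, and a random
  20-gene null set that happens to contain one top-ranked gene reaches a
  near-maximal weighted enrichment score, so permutation q-values over a
  large mixed collection lose power — a property of the weighted
  running-sum statistic itself (the reference GSEA implementation behaves
  identically on the same input), not of this implementation.
- **Imputation recovery** — QRILC on a long censored normal column
  recovers the latent mean and SD to the tolerances stated above.

## Known limitations

- Fits assume imputed matrices are complete; uncertainty from imputation
  is not propagated into the moderated variances (no multiple
  imputation).
- The competitive test's `rho` is a fixed scalar, not estimated from
  data.
- Permutation GSEA power degrades on spiky ranking landscapes (above);
  the consensus rule inherits that conservatism.
- Repeated measures across tissues of the same donor are analyzed per
  tissue, not jointly (no mixed models).
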