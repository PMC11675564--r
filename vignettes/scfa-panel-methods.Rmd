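---
title: "Methods: maternal plasma SCFA panels and child asthma status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal plasma SCFA panels and child asthma status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific setting

Short-chain fatty acids (SCFAs) — acetate, propionate, butyrate, valerate,
isobutyrate, isovalerate and, when detectable, hexanoate — are microbial
fermentation byproducts that circulate in maternal plasma and can cross the
placenta. Acetate in particular is thought to contribute to fetal
immunoprogramming through histone-deacetylase inhibition, and maternal
SCFA levels late in pregnancy have been linked to childhood wheeze and
asthma. `scfapanel` implements the analysis of a two-timepoint pregnancy
design for this question: plasma SCFA panels measured at gestational weeks
20 and 28 (the mid-canalicular and early saccular phases of fetal lung
development) in mothers whose children did (cases) or did not (controls)
later report wheezing or asthma.

The package has two statistical layers:

1. **Level analysis.** For each response — total SCFA concentration, the
   Shannon index of the within-sample SCFA composition, each analyte, and
   each analyte's temporal change (week 28 minus week 20) — an ordinary
   least-squares model

   `response ~ status + BMI + age + income + first-fetus sex + education`

   with a two-sided t-test of the case-indicator coefficient. Unadjusted
   and centered-log-ratio (CLR) sensitivity variants are available.

2. **Interaction dynamics.** For every unordered analyte pair, the
   *difference-in-differences of Pearson correlations*

   `D = [r_case(28w) - r_case(20w)] - [r_ctrl(28w) - r_ctrl(20w)]`,

   tested by a subject-level permutation test: case/control labels are
   shuffled across mothers, each mother's two timepoints travelling
   together, and the two-sided p-value uses the add-one convention
   `p = (1 + #{|D*| >= |D|}) / (n_perm + 1)`.

Because the motivating cohort data are only available under a data-use
agreement, the package ships a synthetic cohort generator whose defaults
emulate the published design, so every stage is testable end to end
without any external data.

## The synthetic cohort generator

`scfa_sim_config()` defaults encode the study conditions:

* 63 control and 64 case mothers, each sampled at weeks 20 and 28
  (254 samples);
* three week-20 samples flagged as quality-control failures, so 124
  week-20 and 127 week-28 samples survive QC;
* a seven-analyte panel with hexanoate as a "rare" analyte detected in
  exactly one sample, which the default prevalence filter removes,
  leaving six analytes;
* covariates drawn to match the published baseline table: BMI normal with
  group means 25.68/25.93 and SDs 5.77/5.75; household income over five
  ordered bands with pooled frequencies 3/23/12/12/50%; first-fetus sex
  male with probability 68/127; education over three bands with
  frequencies 2/9/90%. The source table prints identical mean (sd) values
  for BMI and age — almost certainly a transcription duplication — so we
  use those numbers for BMI and draw age uniformly within the printed
  range (19.51–38.39 years) rather than trusting the duplicated moments.

Concentrations are **log-normal**: the study never states a distribution,
and log-normality is the standard choice for positive, right-skewed
metabolite concentrations. Default medians (uM) are acetate 40,
propionate 4.5, isovalerate 1.3, isobutyrate 1.2, butyrate 1.5, valerate
0.35, hexanoate 0.5, with a common log-scale SD of 0.45 — values in the
range reported for maternal plasma panels. By default the two groups share
every distributional parameter, mirroring the essentially null findings of
the motivating study; `set_mean_shift()` and `set_pair_correlation()`
inject effects for power and recovery experiments, and `null_config()`
strips all group effects for type-I-error studies.

Dependence has two configurable layers on the log scale: a between-analyte
correlation matrix per (group, timepoint) — default exchangeable 0.35 —
and a per-analyte within-subject correlation across the two timepoints
(default 0.5). The joint per-mother covariance couples timepoints through
`sqrt(rho_j rho_k) sd_j sd_k Rbar[j,k]` with `Rbar` the average of the two
between-analyte matrices; when the timepoints share a matrix this is an
exact Kronecker product, so within-timepoint correlations equal the
configured matrices exactly, which the recovery tests exploit. The
assembled covariance is eigen-checked and rejected if not positive
semi-definite; negative within-subject correlations are not supported by
this construction.

Censoring: any generated concentration below its analyte's limit of
quantitation (LOQ) becomes the missing marker. Default LOQs sit two
log-SDs below each analyte's median, censoring roughly 2% of values —
enough to exercise the imputation rule without dominating the data. QC
failures are assigned to uniformly random samples at the configured
timepoint; the data source defines "low quality" only through this flag.

What the generator does **not** emulate: assay batch effects and drift,
heavier-than-log-normal tails, covariate-dependent SCFA levels (covariates
are independent of concentrations by default, though group-specific BMI
means can inject confounding), attrition between timepoints other than
through QC flags, and the twin pregnancy in the original cohort (one
outcome label per mother). Passing tests therefore demonstrate the
*statistical machinery* is correct under a faithful idealisation of the
design, not that any biological conclusion transfers to real cohorts.

## Ingest rules

* **QC:** `apply_qc()` drops flagged samples; mothers keep their surviving
  timepoint and drop out only of the paired (change and correlation)
  analyses.
* **Prevalence filter:** an analyte is detected when its value is present
  and at least its LOQ; analytes detected in fewer than 2 samples (pooled
  over both timepoints, post-QC) are removed. "Detected in only one
  sample" is exactly what the default threshold removes; the denominator
  choice (post-QC, pooled) is ours, as the source does not state one.
* **Half-LOQ imputation:** every missing value becomes `LOQ/2`; observed
  values are never altered. Values reported below the LOQ and values
  absent from the file are treated identically. No model-based
  (e.g. Tobit) imputation is offered — the analysis being reproduced
  specifies the half-LOQ rule only.

## Composition metrics

The Shannon index is computed in natural-log units (nats) on the relative
abundances of the *retained* analytes; with K analytes it lies in
`[0, log K]`. The CLR transform `log x - mean(log x)` is likewise computed
across the retained set; half-LOQ imputation supplies the positivity both
require. The log base for the Shannon index and the analyte set entering
the compositions are package decisions — the source states neither.

## Association models

Income and education enter as unordered dummy-coded factors with the
lowest category as reference; sex is a male indicator; BMI and age are
continuous. Inference on the disease-status coefficient is the classical
OLS t-test — no robust or clustered errors, matching the analysis being
reproduced (models are mother-level; the twin pair is one record). A
factor covariate observed at a single level is dropped from the design
with a warning rather than producing a constant dummy block; a response
with zero variance yields a `degenerate` result row; any remaining rank
deficiency is an error naming the aliased columns. Raw p-values are the
default — the motivating analysis deliberately applied no multiplicity
correction in a hypothesis-generating pilot — with Benjamini–Hochberg
available behind a flag.

## The permutation test

The permutation unit is the **mother**: her week-20 and week-28 samples
travel together under relabelling. This is the only exchangeable null
consistent with paired data — permuting samples independently would break
within-subject dependence and invalidate the test. Group sizes are
preserved, so the post-permutation groups can never fall below the
3-paired-mother minimum the correlation panel requires. Correlations are
computed on the raw (imputed) concentrations, not CLR coordinates, since
the CLR enters the reproduced analysis only as a sensitivity transform for
the level models. The add-one p-value convention guarantees validity and
`p >= 1/(n_perm + 1)`; the default `n_perm = 9999` resolves p-values to
about 1e-4. Label shuffling is unstratified; covariate-stratified
shuffling was considered and left out because the reproduced analysis
describes plain permutation.

## Numerical and design choices

* All randomness flows from explicit integer seeds; equal (config, seed)
  reproduces byte-identical cohorts and result files.
* Correlation-matrix validity is checked with a symmetric eigendecomposition
  at tolerance 1e-8; categorical probabilities must sum to 1 within 1e-9;
  CLR rows sum to zero within 1e-9.
* Ties in the permutation count (`|D*| = |D|`) count as exceedances,
  keeping the test conservative.
* The full pairwise screen shares one permutation stream across all
  `K(K-1)/2` pairs, so per-pair p-values are comparable and the screen
  costs the same as a single pair.

## Validation scale

The package's validation studies (also re-run by `scripts/acceptance.R`)
use sizes chosen to keep Monte-Carlo error well inside the tolerances they
check: 100 random instances for the normal-equations oracle; exhaustive
enumeration over all 70 label assignments of an 8-mother cohort against
50,000 Monte-Carlo permutations; 200 null cohorts at the study design for
the regression type-I error and 300 (at 499 permutations) for the
permutation test; 100 cohorts of 2000 mothers for 1-SD mean-shift
recovery, whose analytic truth on the concentration scale is
`exp(mu + sigma^2/2)(exp(sigma) - 1)`; and 50 cohorts of 1500 mothers with
an injected ±0.2 opposite-direction correlation change for the screen's
ranking power.

## A worked run

```{r, eval = FALSE}
library(scfapanel)

cohort <- simulate_scfa_cohort(scfa_sim_config(), seed = 1)
cohort <- prevalence_filter(apply_qc(cohort))
analysis <- add_profile_metrics(impute_half_loq(cohort))

assoc <- scfa_associations(analysis)
print(assoc)
plot(assoc)

screen <- scfa_didiff(analysis, n_perm = 9999, seed = 1)
print(screen)
plot(screen)
```

## Known limitations

The generator's idealisations listed above; no causal interpretation of
any coefficient; no mixed-effects modelling of the longitudinal structure
(the reproduced analysis is stratified per timepoint plus a change score);
no Fisher-z or partial-correlation alternatives to the permutation test;
and figures are functional reproductions (box plots, annotated heatmap)
rather than styled facsimiles of any published figure.
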