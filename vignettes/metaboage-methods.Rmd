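---
title: "Metabolomic aging models across cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic aging models across cohorts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metaboage)
```

This vignette documents the statistical machinery of `metaboage`, the
assumptions behind it, the tunable parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and design
choices made where the methodology was genuinely open. It states no
empirical result that the test suite does not itself compute.

# The analysis pipeline

The pipeline takes a wide sample × analyte concentration table (key columns
`sample_id`, `subject_id`, `cohort`, `visit`) plus a phenotype table, and
proceeds: variable QC → multivariate outlier removal → between-cohort
calibration → VIF pruning → metabolome-wide association studies (MWAS)
pooled by fixed-effect meta-analysis → four aging models → cross-validated
evaluation → chronological-age-adjusted association analyses.

## Variable QC (`filter_variables`)

Two rules. (1) *Missingness*: an analyte missing in more than
`missing_rule` (default 20%) of samples within any cohort — in particular,
an analyte entirely unmeasured in a cohort — is excluded. (2) *Replicate
reliability*: when a replicate quantification of the same samples is
available (e.g. a re-run under a newer assay protocol), analytes with
replicate Pearson r < 0.7 are excluded. The threshold is conventional for
assay reliability; it is configurable.

## Multivariate outlier weights (`detect_outliers`)

The goal is to remove samples that are jointly (not marginally) atypical
before multivariable modeling. The reference approach in this literature is
pcout-style robust PCA weighting; we implement a contract-compatible
substitute: per cohort, analytes are median/MAD standardized, projected on
principal components retaining 99% of variance, component scores are
MAD-rescaled, and squared score distances are calibrated so their median
matches the chi-square median at the retained dimension. Weights follow a
translated biweight: 1 up to the chi-square 0.5 quantile, a smooth taper to
the 0.999 quantile, and a strictly positive floor (1e-6) beyond. The
published contract is preserved: weights lie in (0, 1], are non-increasing
in the robust score distance, and a sample with weight ≤ 0.1 is flagged as
a location outlier (a threshold of 0 therefore flags nothing). On the
generator's injected outliers (6 robust SDs along a random analyte-space
direction, ≤ 2% of samples) the test suite measures sensitivity 1.0.

## Between-cohort calibration (`calibrate_cohorts`)

Multi-batch NMR panels show multiplicative per-analyte level differences
between cohorts. The calibration procedure in the source literature is
citation-only, so the following was fixed here: demographic strata are
sex × 5-year age band × BMI class (<25, 25–30, ≥30) × ethnicity; for each
non-reference cohort, samples in strata present in both that cohort and the
reference are selected, and per analyte the factor
`median(reference matched) / median(target matched)` is applied
multiplicatively to the whole target cohort. Medians make the factors
robust to residual outliers; multiplicative application preserves
within-cohort relative structure. The reference should be a mixed-sex
cohort in the middle of the study's age range (the generator marks one and
stores it as `reference_cohort`). Whether the original procedure used means
or medians, additive or multiplicative factors, is not documented; this
choice is the package's own and is validated by recovery of the generator's
injected factors (median relative error < 2%) and by idempotence
(recalibrating calibrated data yields factors within 1% of 1).

## VIF pruning (`vif_prune`)

Starting from all analytes, the analyte with the largest variance inflation
factor (VIF_j = 1/(1−R²_j), R²_j from regressing analyte j on all others)
is removed, iterating until all VIF < 5. Implementation: the VIF vector is
the diagonal of the inverse correlation matrix, with a per-variable
regression fallback when that matrix is singular (exact collinearity
surfaces as VIF = +∞ and is removed first). Ties on the maximum are broken
by column order for determinism. The final retained set is verified in the
tests against an independent per-variable R² recomputation.

## MWAS and meta-analysis (`mwas_age`, `mwas_mortality`, `meta_fixed`)

Age MWAS: one linear model per (analyte, cohort), analyte ~ age + sex +
BMI + ethnicity, with the analyte z-scaled *within cohort* so effects are
in SD per year and poolable across cohorts (the scaling locus is the
package's choice; `standardize = FALSE` gives concentration-unit effects
for recovery checks). Covariates constant within a cohort (ethnicity in a
single-ethnicity cohort, sex in a women-only cohort) are dropped
automatically. The age-stratified variant uses strata 20–35, then 5-year
bands to 70, then >70 as the pooled "studies", additionally adjusting for
cohort; z-scaling is then global, since within-stratum scaling would absorb
the very signal under study. Mortality MWAS: per (analyte, cohort) Cox
models adjusted for CA, sex and BMI, Breslow tie handling (ties are
measure-zero in continuous simulated time); ethnicity can be added via
`covars` — the source sections disagree on whether it was included, and
the CA/sex/BMI set is the default.

Pooling is inverse-variance fixed effect: β̂ = Σwᵢbᵢ/Σwᵢ with wᵢ = seᵢ⁻²,
se(β̂) = (Σwᵢ)^(−1/2), Cochran's Q = Σwᵢ(bᵢ−β̂)², I² = max(0, (Q−df)/Q),
labelled high above 0.75 and low below 0.25. Multiplicity is controlled by
Benjamini–Hochberg step-up FDR at q < 0.05, implemented directly and tested
against both a brute-force step-up oracle and `stats::p.adjust`.

# The four aging models

All penalized fits use elastic-net mixing α = 0.5 and select the
regularization strength by internal 10-fold cross-validation at the CV
minimum (a 1-SE option exists; the selection rule is not documented in the
source literature).

- **Elastic net on CA** (`fit_elastic_net_age`): penalized linear
  regression of age on the pruned analyte set via `glmnet`.
- **MARS on CA** (`fit_mars_age`): see below.
- **Phenotypic age** (`fit_phenotypic_age`): an elastic net on CA with
  per-analyte penalty multipliers from the mortality meta-analysis: the
  multiplier is the analyte's pooled mortality p-value (≈0 means almost no
  shrinkage), except analytes whose pooled age and mortality effects point
  in opposite directions get multiplier 1. Pooled meta-analytic p-values
  are used (cohort-specific Cox p-values would be an alternative; the
  source is silent). Penalty factors rely on glmnet's internal rescaling to
  mean 1, so an all-equal vector reproduces the unweighted fit — this
  equivalence is asserted in the tests.
- **Mortality score** (`fit_mortality_score`): elastic-net-penalized Cox
  regression of survival on analytes plus covariates (age, sex, BMI,
  ethnicity, cohort). Covariates carry penalty multiplier 0 — they are
  adjustment variables that must never be dropped, since their
  contributions are excluded afterwards. The score is the linear predictor
  restricted to analyte terms, then affinely rescaled to the training
  sample's CA mean and SD so it reads in years
  (`rescale_to_age_units`: scores′ = (scores−mean)/sd · sd(age) +
  mean(age)).

Published weighted-sum scores are applied from coefficient tables
(`apply_coefficient_table`): per analyte a declared transform (`log`) and
scaling (`cohort_z`, using the scoring dataset's own per-cohort mean/SD —
the source scales "per cohort" without naming a reference), multiplied by
the published weight and summed; analytes missing in some cohorts are k-NN
imputed first (k = 10, the source names the method but not k; distances in
the z-scaled space of analytes observed in every sample). A bundled
*synthetic* 14-analyte template (`inst/extdata/
synthetic_weighted_score_template.csv`) documents the schema; its weights
are invented, not a published model's.

## The MARS engine

Degree-2 multivariate adaptive regression splines, self-contained. A term
is a product of hinge factors max(0, ±(x_v − t)); the forward pass greedily
adds reflected hinge pairs, optionally multiplied into an existing degree-1
term (a parent of degree 2 is never extended, and a variable never repeats
within a term), choosing the (parent, variable, knot) triple that maximally
reduces the residual sum of squares. Candidates are screened by projecting
the candidate pair onto the orthogonal complement of the current basis
(QR factorization computed once per step), so each step is a handful of
BLAS calls rather than thousands of regressions. The pass stops at
`max_terms` (default 21) or when the best relative RSS improvement is below
1e-4. Candidate knots sit at up to 31 equally spaced quantiles per variable
(`knots = "all"` gives exhaustive observed-value knots for oracle testing
— exact knot recovery on noiseless hinges is asserted against an
exhaustive-search oracle).

Backward pruning deletes, at each step, the term whose removal minimizes
GCV = (RSS/n) / (1 − C(M)/n)² with C(M) = M + d·(M−1)/2 and the
conventional interaction penalty d = 3 (configurable), returning the
minimum-GCV model along the deletion path. Coefficients are always the
ordinary least-squares solution on the selected basis (asserted against a
normal-equations oracle). Variable importance is the GCV increase when all
terms involving a variable are removed, rescaled to a maximum of 100.

*A known behavior worth stating plainly*: on pure noise with several
predictors, the forward pass's best-of-(p × knots) spurious candidate gain
is of order (4 + 2·log q)/n · RSS, which approximately equals the GCV
keep/drop cutoff (≈10/n · RSS at d = 3). The greedy search therefore
retains one spurious hinge pair in a sizeable minority of pure-noise runs
when p ≥ 2 — a scale-free property of the method, not of this
implementation. The test suite asserts intercept-only pruning in ≥80% of
seeds where the selection effect is small (single predictor) and a weaker
floor at p = 3.

Models serialize to schema-versioned JSON with doubles encoded as `%.17g`
strings, making the round trip bit-exact (plain JSON number emission loses
the last ulp).

# Evaluation

`kfold_cv` (default k = 7) splits at *subject* level so repeat visits never
straddle folds (the source's splitting unit is unstated; subject-level
prevents leakage); fold assignment is a deterministic function of the seed
and subject list. The pooled CV r is computed over pooled out-of-fold
predictions — not averaged per-fold r — matching "overall" correlation
reporting; per-fold values are also returned. `loco_cv` holds out each
cohort in turn; a cohort with constant age (a birth cohort) reports NA
correlation but a valid MAE. `delta_age` compares within-subject change in
predicted age against change in CA for subjects with two visits, with
per-integer-year medians.

# Association analyses

Linear analyses standardize the score to SD units within each cohort and
regress it on a binary risk factor or a univariate-scaled biomarker,
adjusted for CA, sex and ethnicity; Cox analyses use the score in year
units so the hazard ratio reads per year of metabolomic age beyond CA
("age acceleration"). Both conventions are explicit in the functions rather
than inferred per call. Per-cohort estimates are pooled with the same IVW
machinery as the MWAS (for Cox, on the log hazard scale — the source
implies but does not detail this). Repeat visits are excluded so each
subject counts once; significance is flagged at p < 0.001, a fixed
reporting threshold chosen for the number of independent tests. BMI can be
added in sensitivity analyses (`sensitivity_adjust`), returning paired
base/adjusted rows for attenuation comparison.

# The synthetic generator: what it emulates, what it does not

`sim_config(seed)` materializes every generative parameter once; the
defaults are the package's stated world:

- 8 cohorts × 1500 subjects, age windows (24–45, 30–55, 40–70, 45–65,
  50–75, 55–80, 60–86, 24–86) jointly spanning 24–86 y; 60% female (one
  women-only cohort); two single-ethnicity Finnish-style cohorts; three
  mid/older cohorts with survival follow-up (administrative censoring at 15
  y, baseline hazard 1e-4/y, log HRs 0.08/y of age and −0.3 for female
  sex).
- 98 analytes with residual SD ≈ 1: ~80% carry linear age slopes
  ~N(0, 0.2 SD/decade); 10 carry hinge-shaped effects with knot at age 60
  (±0.3 SD/decade slope change); 12 drive mortality at |log HR| 0.1–0.3 per
  SD, two-thirds concordant with their age trend and one-third opposing it
  (so the opposing-direction penalty rule is exercised).
- Correlation from a 5-factor latent model (factor variance 0.5 of total),
  so VIF pruning has real collinearity to remove; persistent subject-level
  unique effects (variance 0.35) plus fresh per-visit noise (variance
  0.15), so repeat visits are autocorrelated.
- Cohort × analyte multiplicative batch factors ~ lognormal(0, 0.15), the
  reference cohort fixed at 1; 1% multivariate location outliers displaced
  6 robust SDs along a random direction; two cohorts missing one or two
  analytes entirely; 10% of subjects revisited after 10 years.
- A latent biological-age offset (SD 4 y, plus ~3 y for smokers and ~2 y
  for the physically inactive) advances the metabolome relative to CA and
  drives the biomarkers (CRP up, eGFR down, SBP up), giving age-adjusted
  associations a true signal; smoking additionally shifts the three
  strongest age-trend analytes 0.5 SD along their own aging direction.

Not emulated: realistic NMR spectra or units, lipoprotein-physics
consistency between analytes (subfraction sums), non-European population
structure, non-proportional hazards, informative censoring, and any
within-subject autocorrelation structure beyond the random-intercept
stand-in (the true autocorrelation of repeat metabolomes is not
characterized in the source literature — this is flagged, not calibrated).
A green test on this generator establishes that the code recovers the
structure it assumes; it does not establish performance on real cohort
data, whose headline numbers depend on restricted datasets.

# Numerical choices and degenerate inputs

- Constant analytes within a cohort are skipped in MWAS with a warning;
  constant adjustment covariates are dropped per cohort.
- `rescale_to_age_units` refuses constant scores; the mortality score warns
  if its analyte block is entirely shrunk away.
- Log transforms in coefficient tables clamp non-positive values to half
  the smallest positive value (standard metabolomics practice) rather than
  failing.
- Exponential event times are used for survival simulation: all recovery
  checks concern proportional-hazards coefficients, which are agnostic to
  the baseline hazard's shape.
- `k > number of subjects` in CV, fewer than 2 cohorts in LOCO, no repeat
  subjects in `delta_age`, zero events in Cox fits, and empty QC retention
  all raise early, named errors.
- All randomness flows from a single seed through a deterministic child
  seed tree (generator, survival draw, visit selection, CV folds, glmnet
  fold assignment); pipeline reruns under the same config are
  byte-identical, and the manifest records md5 hashes of every output.

# Known limitations

- The outlier weighting is a documented substitute for the reference
  pcout algorithm: the flag contract matches but individual weights will
  not numerically reproduce pcout's.
- The calibration stratum definition (5-year bands, three BMI classes) is a
  fixed design choice; strata empty in either cohort simply drop out of the
  matching, and a cohort sharing no stratum with the reference is a hard
  error.
- The MARS forward pass considers all reflected pairs exactly (no fast-MARS
  heuristics); fits at tens of thousands of samples with the default knot
  grid take on the order of a minute each, so cross-validating MARS at full
  scale is the pipeline's slowest step.
- At default GCV penalty d = 3 the MARS null behavior described above means
  small spurious terms can survive pruning on noise-dominated predictors.
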