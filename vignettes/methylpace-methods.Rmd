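---
title: "Methods: Pace-of-Aging phenotyping and methylation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pace-of-Aging phenotyping and methylation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methylpace implements the full method chain behind pace-of-aging
methylation biomarkers: a longitudinal *Pace of Aging* phenotype built
from repeated organ-system biomarker panels, its distillation into a
sparse CpG scoring algorithm by reliability-filtered elastic-net
regression, deployment of that algorithm on new beta matrices through
quantile normalization against a frozen reference panel, and the
reliability/validity statistics used to evaluate such scores. This
vignette describes the models, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## 1. The Pace of Aging phenotype

The phenotype treats aging as correlated decline across organ systems.
Given a long-format panel of biomarkers measured on the same subjects at
several visit ages (the motivating design is a single-age birth cohort
measured at ages 26, 32, 38 and 45 on 19 biomarkers), the pipeline is:

1. **Baseline standardization** (`standardize_panel()`). Each biomarker is
   z-scored against the mean and SD of its *baseline* (earliest) visit and
   multiplied by its orientation (+1 when an increase indicates
   deterioration). Anchoring at baseline rather than pooling visits keeps
   slope units stable as follow-up extends: later waves carry the
   accumulating between-person divergence, and pooling would shrink the
   scale as more waves arrive. After this step one standardized unit is "one
   baseline-cohort SD", and every biomarker's expected slope is positive.
2. **Growth models** (`fit_growth_model()`). Per biomarker, a linear
   mixed-effects model `value ~ age_c + (1 + age_c || subject)` is fit by
   maximum likelihood (lme4), where `age_c` is visit age centered at the
   mean observed visit age. Centering decorrelates intercepts and slopes;
   given that, the random intercept and random slope are modeled as
   *uncorrelated*. The diagonal model is the standard parsimonious growth
   model here and has a practical benefit: on a balanced design the BLUP of
   the slope decouples exactly into the closed form
   `fixed + lambda * (OLS_i - fixed)` with
   `lambda = tau^2 / (tau^2 + sigma^2 / Sxx)`, which the tests verify
   directly against the fitted conditional modes. Subjects with a single
   visit are not dropped; their BLUP is fully shrunken to the fixed slope.
3. **Fallback estimator.** If the optimizer fails, or the residual variance
   is degenerate (noise-free or perfectly linear trajectories collapse
   `sigma^2` to zero and make the ML fit ill-conditioned), the fit switches
   to a two-stage estimator: per-subject OLS slopes, moment estimates of
   `tau^2` and `sigma^2`, and the same closed-form shrinkage. The fallback
   is flagged in the fit object (`method = "two-stage"`). In the noise-free
   limit `lambda = 1`, so the fallback returns the per-subject OLS slopes —
   exactly the planted truth. The two-stage path can also be requested
   explicitly (`method = "two-stage"`); being closed-form it has no
   optimizer noise, which matters for the invariance discussion below.
4. **Compositing** (`compute_pace()`). Each subject's slopes are summed
   across biomarkers and divided by the cohort mean of the raw composite, so
   the cohort mean is exactly 1 — "one biological year per chronological
   year". Division (rather than an affine map) preserves ratios, which is
   how pace values are read ("1.5 years per year"). A non-positive cohort
   mean composite raises an error instead of silently flipping signs: in
   practice it means biomarker orientations are misconfigured. Subjects
   missing a biomarker's slope receive the cohort mean slope for that
   biomarker (imputations are counted); subjects missing more than half the
   biomarkers are excluded from scaling and reported, since composites over
   very different biomarker subsets are not comparable.

**Numerical reproducibility of the ML path.** Standardization absorbs any
positive rescaling of a biomarker's raw values essentially exactly
(differences below 1e-12), so the pace composite is scale-invariant in
exact arithmetic. On the ML path the realized invariance is limited by
optimizer reproducibility: the profiled deviance is nearly flat when the
slope variance sits close to its boundary, and perturbing inputs at the
last floating-point digit can move the stopping point enough to shift
BLUPs by ~1e-6 (composite differences up to ~1e-5; tightening the
optimizer tolerances does not change this, because the flatness is a
property of the surface, not the stopping rule). The closed-form two-stage
path is invariant to below 1e-8. The test suite asserts all three facts at
those levels.

## 2. Probe reliability (ICC)

Technical replicates are interchangeable aliquots, so reliability is the
one-way random-effects, single-measurement, absolute-agreement ICC:
`sigma2_between / (sigma2_between + sigma2_within)` from the one-way ANOVA
decomposition, with the mean-replicate-count correction for unbalanced
designs. Negative between-sample variance estimates are truncated at zero
and flagged (standard ANOVA practice; it preserves the `[0,1]` filter
semantics). Confidence intervals use Searle's F-distribution interval —
closed-form, no resampling. `probe_icc_table()` applies the estimator
probewise (vectorized for balanced designs); probes with zero total
variance get `NA` rather than aborting the table. `filter_probes()` is
*strict* (`ICC > threshold`, default 0.4), and the boundary behavior is
unit-tested. Whether the source analyses used ANOVA moments or REML for
their replicate ICCs is not derivable from the published description; the
ANOVA estimator is used here and validated against its closed form and
against the inter-replicate Pearson correlation.

At a 200-samples-by-2-replicates design the estimator's Monte Carlo SE for
a true ICC of 0.75 is about 0.044; calibration checks therefore average
over independent simulated datasets rather than judging a single draw.

## 3. Training the CpG scoring algorithm

`train_elastic_net()` restricts predictors to the reliable probe set, then
fits an elastic net (glmnet) of the pace phenotype on beta values with
mixing parameter `alpha = 0.5` by default. Predictors are standardized
internally for fitting and coefficients returned on the beta scale, so
scoring needs no stored scale parameters. The penalty is chosen at the
minimum mean 10-fold cross-validated squared error, with fold assignment
deterministic given the seed; the published method this follows reports a
single selected penalty without a 1-SE rule, so CV-minimum is the default
and `lambda_rule = "1se"` is available.

The two rules trade sensitivity against selection purity, and no single
rule delivers both at the simulated defaults: at n = 500 with 50 causal
probes out of 2000, CV-minimum recovers ≥60% of causal probes but keeps
many small-coefficient noise probes (false-discovery fraction near 0.5),
while the 1-SE rule drives false discoveries to ~5% at the cost of
sensitivity (~0.5). This is classic CV-minimum over-selection, not an
implementation artifact; prediction (the deployment goal) is served by
CV-minimum, support recovery by 1-SE. The property tests check each
guarantee under the rule that provides it.

One asymmetry is inherited from the published description and left
explicit: training uses raw betas while scoring uses reference-normalized
values. On synthetic data this costs little (held-out correlation ~0.97 at
the defaults), and resolving it would require information the source does
not provide.

**Reference panel.** `build_reference_panel()` freezes, at training time,
the ordered union of all weighted probes and background probes sampled
without replacement from the remaining universe — by default stratified
across deciles of training-set mean beta, so the panel represents the
underlying beta distribution by construction rather than only in
expectation (simple random sampling is available by flag). The published
panel construction draws 19,827 background probes to join a 173-probe
algorithm in a 20,000-probe panel; the builder reproduces exactly this
structure for any weight table. Each panel probe stores its training-set
mean beta; the *sorted vector of these reference means* is the
quantile-normalization target. No sampling ever happens at scoring time.

Models serialize to a directory (`weights.csv`, `panel.csv`, `model.json`)
with shortest-exact decimal formatting, so save/load round-trips are
bit-lossless; loading integrity-checks that every weighted probe is in the
panel and that reference means lie in `[0,1]`. Externally published weight
tables (probe_id/weight CSV with an `intercept` row) load through the same
reader and combine with a separately built panel.

## 4. Scoring new samples

`score()` runs: align the target matrix to the panel (missing probes
become missing rows) → missingness gate → per-sample quantile
normalization to the reference → weighted sum
`intercept + sum_j w_j * normalized_beta_j`. Scoring is deterministic; no
randomness exists at scoring time.

* **Missingness gate**: samples with under 80% of algorithm probes or
  under 80% of panel probes present are refused with a reason (both
  thresholds configurable). Cross-array application makes missing probes
  routine, and scoring a sample whose algorithm probes are mostly absent
  would be silently meaningless.
* **Imputation order**: missing values are imputed with the probe's
  reference mean *before* normalization, keeping each sample's rank vector
  complete so the rank→target map is well-defined.
* **Normalization**: per sample, independently (samples are scored
  individually against the reference, so one sample's values never affect
  another's score), each value is replaced by the reference target value
  at its within-sample rank; ties receive the mean of the tied target
  positions (the standard convention; its bit-exactness is unit-tested).
  No jitter is added — determinism outranks distributional smoothness.
* **No target-cohort recentering**: the score inherits the training scale;
  normalization is to the reference, not to the target cohort.

The headline property this buys is **rank invariance**: any strictly
increasing per-sample transformation of the target matrix (the monotone
batch distortions the generator produces — affine compression, logit
shifts, power curves) leaves scores *bit-identical* when no values are
missing. The acceptance suite verifies this at 200 samples by 20,000
panel probes.

## 5. Comparator biological-age algorithms

These are the standard physiology-based comparators, panel-agnostic and
trained on whatever reference table is supplied (the conventional
8-biomarker blood-chemistry/BP/FEV1 panel ships as metadata with log
flags, but nothing is hard-coded):

* **Klemera–Doubal biological age**: precision-weighted inverse
  regression, `BA = sum((x_j - q_j) k_j / s_j^2) / sum(k_j^2 / s_j^2)`
  from per-biomarker OLS fits of marker on age. The non-augmented form is
  the default (the published comparator cites an implementation without
  printing the chronological-age augmentation term); the augmented variant
  is available by flag with a user-supplied `s_ba`. Exact identity: a
  profile lying on every regression line at age `a` returns `BA = a`.
* **Phenotypic Age (functional form)**: linear predictor → Gompertz
  cumulative mortality risk over a configured horizon → inversion through
  an age-only calibration to years. All constants (coefficients, Gompertz
  shape, horizon, age calibration) are configuration data, never
  hard-coded; the published coefficient sets can be supplied as such. The
  risk round trip is analytically the identity in the linear predictor, so
  the implementation computes the risk explicitly (tested against
  numerical inversion to 1e-6) and clamps only where risk saturates in
  floating point, falling back to the equivalent linear-predictor
  inversion there.
* **Homeostatic dysregulation**: `log(1 + Mahalanobis distance)` from a
  healthy reference centroid, the healthy subset defaulting to the
  youngest age tertile of the training table (the source does not specify
  its subset rule; the tertile is configurable). Identity covariance
  reduces it to `log(1 + Euclidean)`; affine marker rescaling (with
  refit) leaves it unchanged. References whose healthy covariance is
  rank-deficient are refused with advice, or can be fit markers-only for
  KDM/PhenoAge use (`dysregulation = FALSE`) — deterministic toy data is
  the canonical case.
* **Age acceleration**: OLS residuals of a measure on chronological age;
  `effect sizes`: Cohen's d with the Hedges-style large-sample interval
  and Pearson r with the Fisher-z interval.

## 6. What the synthetic generators emulate — and what they do not

`simulate_longitudinal_cohort()` plants a latent pace per subject (mean
exactly 1 by construction, SD exactly `pace_sd`, default 0.29 matching the
dispersion reported for this phenotype) that loads linearly on every
biomarker's rate of change, plus subject-level intercepts, slope
deviations and visit noise. Defaults: 19 biomarkers, visits at ages
26/32/38/45, mean slopes and pace loadings of 0.02–0.06 standardized
units/year (about 0.5–1 baseline SD of drift over two decades), intercept
SD 1, slope-deviation SD 0.01, residual SD 0.3. A single latent factor is
a modeling choice for testability — it makes "recover the planted pace" a
well-posed criterion — and not a claim about the joint slope distribution
of any real cohort.

`simulate_methylation()` generates betas on a logistic latent scale
(linear signal lives on an unbounded scale; the squashing keeps values
strictly inside (0,1)), with a sparse causal probe set (default 50 of
2000) carrying linear pace signal of SD 0.5 against sample noise of SD
0.2. At these settings OLS on the causal probes alone recovers the pace
with r ≥ 0.9 — the oracle ceiling the trainer is judged against.
`simulate_replicates()` adds per-probe technical error sized so the
variance-components ICC equals the planted target, counts values clipped
to [0,1], and refuses to continue if more than 1% clip (silent clipping
would corrupt the planted reliabilities). `apply_monotone_distortion()`
produces the strictly increasing per-sample maps used by the
rank-invariance tests.

Not emulated: probe-level genomic annotation, cell-type composition,
array chemistry (Type I/II probe designs), batch structure beyond
monotone per-sample distortion, nonlinear trajectories, informative
dropout. Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms — not that any real cohort's published
coefficients or cohort-level correlations are reproduced, which would
require the original restricted data.

## 7. Problem sizes and determinism

Simulation-based checks in the test suite and acceptance script use
cohorts of 50–500 subjects, probe universes of 500–21,000, and 5–20
seeds per property; these sizes were chosen so every quantity is stable
at its stated tolerance while the whole suite stays desk-scale. All
generators are pure functions of their configuration including the seed;
every stochastic pipeline stage (fold assignment, background draw)
consumes an explicit seed, and scoring consumes none.
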