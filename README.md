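# methylpace

Aging is progressive decline across organ systems, and its *pace* varies
widely between people of the same chronological age. **methylpace** is an R
toolkit for the full method chain behind pace-of-aging DNA-methylation
biomarkers, aimed at biomarker developers and methods researchers who want
every stage of that chain as reusable, testable components:

1. **Pace of Aging phenotype** — per-biomarker linear mixed-effects growth
   models on longitudinal panels (random slopes μ<sub>1iB</sub> per subject
   *i*, biomarker *B*), composited as
   Pace<sub>i</sub> = Σ<sub>B</sub> μ<sub>1iB</sub> and scaled so the
   cohort mean is exactly 1 biological year per chronological year.
2. **Probe reliability** — one-way random-effects ICC
   σ²<sub>b</sub>/(σ²<sub>b</sub>+σ²<sub>w</sub>) from technical
   replicates, with F-based confidence intervals and a strict
   ICC &gt; 0.4 filter for training probes.
3. **Elastic-net distillation** — glmnet (α = 0.5, penalty by
   cross-validation) of the phenotype on reliability-filtered beta values,
   frozen together with a reference normalization panel (algorithm probes
   plus decile-stratified background probes, each carrying its training-set
   mean beta).
4. **Scoring** — new samples are aligned to the panel,
   quantile-normalized per sample to the sorted reference means, and scored
   as intercept + Σ<sub>j</sub> w<sub>j</sub>·β̃<sub>j</sub>. Scores are
   *bit-identical* under any strictly increasing per-sample distortion of
   the input — the property the reference-quantile design exists for.
5. **Comparators** — Klemera–Doubal biological age, the Phenotypic Age
   functional form (Gompertz risk inversion), homeostatic dysregulation
   (log Mahalanobis distance from a healthy centroid), age-acceleration
   residuals, Cohen's d and Pearson r with confidence intervals.
6. **Synthetic data** — generators that plant a known latent pace, causal
   CpG sets, probe-level reliability, and monotone batch distortions, so
   every estimator above can be validated by parameter recovery without any
   external data.

Published CpG weight tables for this family of algorithms (probe/weight
CSV with an intercept row) load directly and combine with a locally built
reference panel; the package never requires them.

## Worked example

```r
library(methylpace)

# 1. a synthetic birth cohort: 300 subjects, 19 biomarkers, 4 visit waves
sim <- simulate_longitudinal_cohort(300, seed = 7)
sim$panel
#> <biomarker_panel> 22800 observations | 300 subjects | 19 biomarkers | visit ages: 26, 32, 38, 45

# 2. Pace of Aging from growth models
pace <- pace_of_aging(sim$panel)
round(c(mean = mean(pace$pace), sd = sd(pace$pace),
        truth_r = cor(pace$pace, sim$truth$latent_pace[pace$subject_id])), 3)
#>    mean      sd truth_r
#>   1.000   0.101   0.901

# 3. methylation with planted CpG signal; reliability-filter the probes
meth <- simulate_methylation(sim$truth$latent_pace, n_probes = 2000,
                             n_causal = 50, seed = 8)
planted_icc <- rep(c(0.2, 0.7), length.out = 2000)  # half unreliable probes
reps <- simulate_replicates(meth$betas, target_icc = planted_icc, seed = 9)
reliable <- filter_probes(probe_icc_table(reps), threshold = 0.4)
c(retained = length(reliable), total = nrow(meth$betas))
#> retained    total
#>     1000     2000

# 4. train, freeze the reference panel, score held-out samples
train_ids <- colnames(meth$betas)[1:200]
test_ids  <- colnames(meth$betas)[201:300]
w <- train_elastic_net(meth$betas[, train_ids], pace, reliable, seed = 10)
w
#> <weight_table> 73 weighted probes | intercept 1.563 | alpha = 0.5, lambda = 0.008238084
panel <- build_reference_panel(w, meth$betas[, train_ids],
                               panel_size = 2000, seed = 11)
model <- trained_model(w, panel)
scores <- score(meth$betas[, test_ids], model)
round(c(heldout_r = cor(scores$score, sim$truth$latent_pace[test_ids])), 3)
#> heldout_r
#>     0.937

# 5. scores are invariant to monotone per-sample batch distortion
distorted <- apply_monotone_distortion(meth$betas[, test_ids], "power", seed = 12)
identical(score(distorted, model)$score, scores$score)
#> [1] TRUE
```

Reading the numbers: the scaled composite has cohort mean exactly 1 by
construction, and its SD (0.101 here) reflects the synthetic cohort's
planted heterogeneity filtered through estimation noise. The held-out
correlation of 0.937 says the frozen 73-CpG model, applied through panel
alignment and reference-quantile normalization to samples it never saw,
recovers the latent pace those samples were generated from. The final
`TRUE` is the normalization guarantee: a monotone per-sample distortion
(here a power curve, emulating a batch effect) changes the input betas but
not a single bit of the scores.

A thin command-line surface wraps the same functions
(`Rscript inst/cli/methylpace.R <simulate|pace|icc|train|score|bioage> --help`;
exit codes 0/2/3/4 for success/usage/data/numerical errors).

## Scope

The package implements the *methods*: it does not ship any cohort's
measured data, published clock coefficient sets, or survival analyses, and
synthetic results validate algorithmic correctness rather than reproduce
cohort-level findings (see the methods vignette,
`vignettes/methylpace-methods.Rmd`, for the models, defaults, numerical
choices and limitations).
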