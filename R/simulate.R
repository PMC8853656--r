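# Synthetic-data generators. Each one plants a known ground truth (latent
# pace, causal probes, probe-level reliability) so downstream estimators can
# be validated by parameter recovery rather than against external data.

#' Simulate a single-age birth cohort with repeated biomarker panels
#'
#' Generates a longitudinal biomarker panel in which every subject is seen at
#' the same set of visit ages (default 26, 32, 38, 45 years) on `n_biomarkers`
#' biomarkers (default 19). Each subject carries a latent pace of aging
#' (cohort mean exactly 1, SD exactly `pace_sd`) that loads on the
#' per-biomarker rates of change: for subject i, biomarker B and visit age a,
#'
#'   value = intercept_iB + slope_iB * (a - mean(visit_ages)) + noise
#'   slope_iB = mean_slope_B + loading_B * (pace_i - 1) + deviation_iB
#'
#' Values are emitted in a standardized sign convention: every biomarker's
#' mean slope is positive, i.e. higher values indicate deterioration
#' (orientation +1 in the metadata).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param visit_ages strictly increasing visit ages in years.
#' @param n_biomarkers number of biomarkers.
#' @param pace_sd dispersion of the latent pace around 1.
#' @param mean_slope_range range of per-biomarker mean slopes
#'   (standardized units per year).
#' @param slope_loading_range range of per-biomarker loadings of the slope on
#'   the latent pace (standardized units per year per unit pace).
#' @param intercept_sd SD of subject-by-biomarker random intercepts.
#' @param slope_dev_sd SD of subject-by-biomarker slope deviations not
#'   explained by the latent pace.
#' @param residual_sd SD of visit-level measurement noise.
#' @param seed RNG seed; the output is a pure function of the arguments
#'   including the seed.
#' @return A list with elements `panel` (a [biomarker_panel()]) and `truth`
#'   (latent pace per subject, true per-subject-per-biomarker slopes, and the
#'   biomarker-level mean slopes and loadings).
#' @export
simulate_longitudinal_cohort <- function(n_subjects,
                                         visit_ages = c(26, 32, 38, 45),
                                         n_biomarkers = 19,
                                         pace_sd = 0.29,
                                         mean_slope_range = c(0.02, 0.06),
                                         slope_loading_range = c(0.02, 0.06),
                                         intercept_sd = 1,
                                         slope_dev_sd = 0.01,
                                         residual_sd = 0.3,
                                         seed = NULL) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    stop_config("n_subjects must be an integer >= 2")
  }
  if (length(visit_ages) < 2 || any(diff(visit_ages) <= 0)) {
    stop_config("visit_ages must contain >= 2 strictly increasing ages")
  }
  if (!is_count(n_biomarkers) || n_biomarkers < 1) {
    stop_config("n_biomarkers must be a positive integer")
  }
  if (!is.numeric(pace_sd) || pace_sd <= 0) stop_config("pace_sd must be > 0")
  for (nm in c("intercept_sd", "slope_dev_sd", "residual_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop_config(sprintf("%s must be a single value >= 0", nm))
    }
  }

  run_seeded(seed, function() {
    n <- as.integer(n_subjects)
    nb <- as.integer(n_biomarkers)
    subjects <- sprintf("S%04d", seq_len(n))
    biomarkers <- sprintf("bm%02d", seq_len(nb))

    # latent pace: standardized draw rescaled so mean is exactly 1 and the
    # sample SD exactly pace_sd (the planted dispersion, not an estimate)
    z <- rnorm(n)
    z <- (z - mean(z)) / sd(z)
    pace <- 1 + pace_sd * z
    names(pace) <- subjects

    mean_slope <- runif(nb, mean_slope_range[1], mean_slope_range[2])
    loading <- runif(nb, slope_loading_range[1], slope_loading_range[2])

    dev <- matrix(rnorm(n * nb, 0, slope_dev_sd), n, nb)
    true_slopes <- outer(pace - 1, loading) + matrix(mean_slope, n, nb, byrow = TRUE) + dev
    dimnames(true_slopes) <- list(subjects, biomarkers)

    u0 <- matrix(rnorm(n * nb, 0, intercept_sd), n, nb)
    age_c <- visit_ages - mean(visit_ages)
    nv <- length(visit_ages)

    # long format: subject varies slowest, then biomarker, then visit
    idx_s <- rep(seq_len(n), each = nb * nv)
    idx_b <- rep(rep(seq_len(nb), each = nv), times = n)
    idx_v <- rep(seq_len(nv), times = n * nb)
    value <- u0[cbind(idx_s, idx_b)] +
      true_slopes[cbind(idx_s, idx_b)] * age_c[idx_v] +
      rnorm(n * nb * nv, 0, residual_sd)

    data <- data.frame(
      subject_id = subjects[idx_s],
      visit_age = visit_ages[idx_v],
      biomarker_id = biomarkers[idx_b],
      value = value,
      stringsAsFactors = FALSE
    )
    meta <- data.frame(
      biomarker_id = biomarkers,
      orientation = 1L,
      name = paste("Synthetic biomarker", seq_len(nb)),
      stringsAsFactors = FALSE
    )
    list(
      panel = biomarker_panel(data, meta),
      truth = list(latent_pace = pace, true_slopes = true_slopes,
                   mean_slope = setNames(mean_slope, biomarkers),
                   loading = setNames(loading, biomarkers))
    )
  })
}

#' Simulate a methylation beta matrix with planted CpG signal
#'
#' Betas are generated on an unbounded latent (logit) scale — causal probes
#' carry a linear signal of the latent pace, all probes get probe-level
#' baseline and visit noise — then squashed through the logistic function
#' into (0,1). Probe IDs are Illumina-style `cg########` strings.
#'
#' @param pace numeric vector of per-sample pace values (optionally named by
#'   sample ID).
#' @param n_probes number of probes in the simulated universe.
#' @param n_causal number of causal probes (`<= n_probes`).
#' @param effect_sd SD of the causal-probe effect sizes on the latent scale.
#' @param noise_sd SD of sample-level noise on the latent scale.
#' @param base_mean_sd SD of probe baseline levels on the latent scale
#'   (controls how betas spread across (0,1)).
#' @param seed RNG seed.
#' @return A list with `betas` (probes x samples matrix, values strictly in
#'   (0,1)) and `truth` (causal probe IDs and their latent-scale effects).
#' @export
simulate_methylation <- function(pace, n_probes = 2000, n_causal = 50,
                                 effect_sd = 0.5, noise_sd = 0.2,
                                 base_mean_sd = 1, seed = NULL) {
  if (!is.numeric(pace) || !all(is.finite(pace))) {
    stop_config("pace must be a finite numeric vector")
  }
  if (!is_count(n_probes) || !is_count(n_causal) || n_causal > n_probes) {
    stop_config("need integer counts with n_causal <= n_probes")
  }
  if (effect_sd < 0 || noise_sd < 0) stop_config("noise scales must be >= 0")

  run_seeded(seed, function() {
    ns <- length(pace)
    samples <- names(pace) %||% sprintf("sample_%04d", seq_len(ns))
    probes <- cg_probe_ids(n_probes)
    causal_idx <- sort(sample.int(n_probes, n_causal))
    base <- rnorm(n_probes, 0, base_mean_sd)
    eff <- numeric(n_probes)
    eff[causal_idx] <- rnorm(n_causal, 0, effect_sd)
    z <- base + outer(eff, pace - 1) + matrix(rnorm(n_probes * ns, 0, noise_sd), n_probes, ns)
    betas <- plogis(z)
    dimnames(betas) <- list(probes, samples)
    list(
      betas = betas,
      truth = list(causal_probes = probes[causal_idx],
                   effects = setNames(eff[causal_idx], probes[causal_idx]))
    )
  })
}

#' Simulate technical replicate beta matrices with planted reliability
#'
#' Treats each probe's values in `base` as the sample-level (biological)
#' component and adds independent technical error per replicate, with the
#' per-probe error variance chosen so the variance-components intraclass
#' correlation, between / (between + error), equals `target_icc`. Values are
#' clipped back to \[0,1\]; the generator refuses to proceed silently if more
#' than `max_clip_frac` of values clip, because clipping corrupts the
#' planted reliabilities.
#'
#' @param base probes x samples beta matrix (the sample-level component).
#' @param target_icc planted ICC in (0,1]; scalar or one value per probe.
#' @param n_reps number of replicates (>= 2).
#' @param seed RNG seed.
#' @param max_clip_frac maximum tolerated fraction of clipped values.
#' @return A list of `n_reps` beta matrices with the same dimnames as `base`,
#'   with attribute `clip_fraction` recording the realized clip fraction.
#' @export
simulate_replicates <- function(base, target_icc, n_reps = 2, seed = NULL,
                                max_clip_frac = 0.01) {
  if (!is.matrix(base) || !is.numeric(base)) stop_config("base must be a numeric matrix")
  if (!is_count(n_reps) || n_reps < 2) stop_config("n_reps must be an integer >= 2")
  if (!is.numeric(target_icc) || any(target_icc <= 0) || any(target_icc > 1)) {
    stop_data("target_icc must lie in (0, 1]")
  }
  if (!length(target_icc) %in% c(1L, nrow(base))) {
    stop_config("target_icc must be a scalar or one value per probe")
  }
  icc <- rep_len(target_icc, nrow(base))

  run_seeded(seed, function() {
    sigma_b <- apply(base, 1, sd)
    sigma_e <- sigma_b * sqrt((1 - icc) / icc)
    n_clip <- 0L
    reps <- lapply(seq_len(n_reps), function(r) {
      e <- matrix(rnorm(length(base)), nrow(base), ncol(base)) * sigma_e
      x <- base + e
      clipped <- x < 0 | x > 1
      n_clip <<- n_clip + sum(clipped)
      x[x < 0] <- 0
      x[x > 1] <- 1
      dimnames(x) <- dimnames(base)
      x
    })
    clip_frac <- n_clip / (length(base) * n_reps)
    if (clip_frac > max_clip_frac) {
      stop_data(sprintf(
        "%.2f%% of replicate values clipped to [0,1] (limit %.2f%%); planted ICCs would be corrupted",
        100 * clip_frac, 100 * max_clip_frac))
    }
    attr(reps, "clip_fraction") <- clip_frac
    reps
  })
}

#' Apply a strictly increasing per-sample distortion to a beta matrix
#'
#' Each sample (column) is passed through its own strictly increasing map
#' from \[0,1\] into \[0,1\], with per-sample parameters drawn from the seed.
#' Within-sample rank order is preserved exactly, which is the property the
#' reference-quantile scorer is designed to be invariant to.
#'
#' @param m probes x samples beta matrix.
#' @param distortion one of `"identity"`, `"affine-compress"`
#'   (x -> a + b x with a >= 0, a + b <= 1), `"logit-shift"`
#'   (x -> plogis(qlogis(x) + delta)), `"power"` (x -> x^p, p > 0).
#' @param seed RNG seed for the per-sample parameters.
#' @return The distorted matrix, with attribute `distortion_params`.
#' @export
apply_monotone_distortion <- function(m,
                                      distortion = c("identity", "affine-compress",
                                                     "logit-shift", "power"),
                                      seed = NULL) {
  if (!is.matrix(m) || !is.numeric(m)) stop_config("m must be a numeric matrix")
  if (length(distortion) != 1 || !distortion %in% c("identity", "affine-compress",
                                                    "logit-shift", "power")) {
    stop_config(sprintf("unknown distortion_id: %s",
                        paste(distortion, collapse = ", ")))
  }
  if (distortion == "identity") {
    attr(m, "distortion_params") <- data.frame(sample = colnames(m) %||% seq_len(ncol(m)))
    return(m)
  }
  run_seeded(seed, function() {
    ns <- ncol(m)
    out <- m
    params <- switch(distortion,
      "affine-compress" = {
        a <- runif(ns, 0, 0.1)
        b <- runif(ns, 0.6, 1 - a)
        for (j in seq_len(ns)) out[, j] <- a[j] + b[j] * m[, j]
        data.frame(a = a, b = b)
      },
      "logit-shift" = {
        delta <- runif(ns, -1, 1)
        for (j in seq_len(ns)) out[, j] <- plogis(qlogis(m[, j]) + delta[j])
        data.frame(delta = delta)
      },
      "power" = {
        p <- runif(ns, 0.5, 2)
        for (j in seq_len(ns)) out[, j] <- m[, j]^p[j]
        data.frame(p = p)
      })
    attr(out, "distortion_params") <- params
    out
  })
}
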