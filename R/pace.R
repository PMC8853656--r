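# Longitudinal Pace of Aging: baseline standardization, per-biomarker
# mixed-effects growth models with BLUP random slopes, and the sign-oriented
# composite scaled to a cohort mean of 1.

#' Standardize a biomarker panel against its baseline visit
#'
#' Each biomarker is z-scored using the mean and SD of its values at the
#' baseline (earliest observed) visit age, then multiplied by its
#' orientation so that for every biomarker a positive slope means
#' deterioration. Anchoring the scale at baseline keeps slope units stable
#' as follow-up extends.
#'
#' @param panel a [biomarker_panel()].
#' @return A standardized `biomarker_panel` (orientation +1 for all
#'   biomarkers after orientation is folded into the values), with
#'   attribute `standardization` recording the per-biomarker baseline
#'   mean/SD used.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "biomarker_panel"))
  d <- panel$data
  meta <- panel$meta
  orient <- setNames(meta$orientation, meta$biomarker_id)
  stats_list <- list()
  for (b in unique(d$biomarker_id)) {
    rows <- d$biomarker_id == b
    base_age <- min(d$visit_age[rows])
    at_base <- d$value[rows & d$visit_age == base_age]
    m <- mean(at_base, na.rm = TRUE)
    s <- sd(at_base, na.rm = TRUE)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      stop_data(sprintf(
        "biomarker '%s' has zero variance at its baseline visit (age %s); cannot standardize",
        b, base_age))
    }
    d$value[rows] <- orient[[b]] * (d$value[rows] - m) / s
    stats_list[[b]] <- data.frame(biomarker_id = b, baseline_age = base_age,
                                  baseline_mean = m, baseline_sd = s,
                                  orientation = orient[[b]])
  }
  meta$orientation <- 1L
  out <- biomarker_panel(d, meta)
  attr(out, "standardization") <- do.call(rbind, stats_list)
  out
}

#' Fit a random-slope growth model for one biomarker
#'
#' Fits `value ~ age_c + (1 + age_c || subject)` by maximum likelihood,
#' where `age_c` is visit age centered at the mean observed visit age, and
#' returns the BLUP (conditional-mode) per-subject slopes. Random intercept
#' and slope are modeled as uncorrelated: with centered age the
#' intercept-slope coupling is negligible by design and the diagonal model
#' is the standard parsimonious growth model. If the optimizer fails, or
#' the residual variance is degenerate (e.g. noise-free trajectories), the
#' fit falls back to a two-stage estimator — per-subject OLS slopes shrunk
#' toward the fixed slope by lambda = tau^2 / (tau^2 + sigma^2/Sxx) — and
#' flags the fallback in the returned object. Subjects with a single visit
#' receive fully shrunken slopes (the fixed slope) rather than being
#' dropped.
#'
#' @param panel a (typically standardized) [biomarker_panel()].
#' @param biomarker_id which biomarker to fit.
#' @param min_subjects minimum number of subjects with >= 2 visits.
#' @param method `"auto"` (maximum likelihood, falling back to the
#'   two-stage estimator on failure or degenerate residual variance) or
#'   `"two-stage"` (force the closed-form shrinkage estimator, which is
#'   exactly scale-invariant and has no optimizer noise).
#' @return An object of class `growth_model_fit`: biomarker id, fixed
#'   intercept/slope, named vector of per-subject BLUP slopes, variance
#'   components (intercept, slope, residual), number of subjects, the age
#'   center used, and the estimation `method` ("lmm", "two-stage" or
#'   "degenerate").
#' @export
fit_growth_model <- function(panel, biomarker_id, min_subjects = 10,
                             method = c("auto", "two-stage")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "biomarker_panel"))
  d <- panel$data[panel$data$biomarker_id == biomarker_id, , drop = FALSE]
  if (!nrow(d)) stop_data(sprintf("biomarker '%s' not present in panel", biomarker_id))
  visits <- table(d$subject_id)
  if (sum(visits >= 2) < min_subjects) {
    stop_data(sprintf(
      "biomarker '%s' observed with >= 2 visits for only %d subjects (need >= %d)",
      biomarker_id, sum(visits >= 2), min_subjects))
  }
  age_center <- mean(d$visit_age)
  d$age_c <- d$visit_age - age_center

  if (var(d$value) < .Machine$double.eps) {
    subjects <- sort(unique(d$subject_id))
    return(new_growth_fit(biomarker_id, 0, 0,
                          setNames(rep(0, length(subjects)), subjects),
                          c(intercept = 0, slope = 0, residual = 0),
                          age_center, "degenerate"))
  }

  if (method == "two-stage") {
    return(two_stage_growth_fit(d, biomarker_id, age_center))
  }

  diag_msgs <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lme4::lmer(value ~ age_c + (1 + age_c || subject_id),
                                  data = d, REML = FALSE)),
      warning = function(w) {
        diag_msgs <<- c(diag_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) e
  )
  use_fallback <- inherits(fit, "error")
  if (!use_fallback) {
    sigma2 <- stats::sigma(fit)^2
    # perfectly linear trajectories: residual variance collapses and BLUPs
    # are ill-conditioned; the two-stage path is exact there (lambda -> 1)
    use_fallback <- sigma2 < 1e-10 * var(d$value)
  }
  if (use_fallback) {
    return(two_stage_growth_fit(d, biomarker_id, age_center))
  }

  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$subject_id
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$var1 == "(Intercept)" & !is.na(vc$var1)][1]
  var_slope <- vc$vcov[vc$var1 == "age_c" & !is.na(vc$var1)][1]
  var_resid <- stats::sigma(fit)^2
  slopes <- setNames(fe[["age_c"]] + re[["age_c"]], rownames(re))
  # subjects present in data but absent from the random-effect frame
  # (cannot happen with lmer, but keep the contract explicit)
  missing_subj <- setdiff(unique(d$subject_id), names(slopes))
  if (length(missing_subj)) {
    slopes[missing_subj] <- fe[["age_c"]]
  }
  out <- new_growth_fit(biomarker_id, fe[["(Intercept)"]], fe[["age_c"]],
                        slopes[sort(names(slopes))],
                        c(intercept = var_int %||% 0, slope = var_slope %||% 0,
                          residual = var_resid),
                        age_center, "lmm")
  # optimizer diagnostics travel with the fit instead of as loose warnings
  out$diagnostics <- diag_msgs
  out
}

new_growth_fit <- function(biomarker_id, fixed_intercept, fixed_slope, slopes,
                           varcomp, age_center, method) {
  structure(list(biomarker_id = biomarker_id,
                 fixed_intercept = unname(fixed_intercept),
                 fixed_slope = unname(fixed_slope),
                 slopes = slopes,
                 varcomp = varcomp,
                 n_subjects = length(slopes),
                 age_center = age_center,
                 method = method),
            class = "growth_model_fit")
}

# Two-stage fallback: per-subject OLS slopes, moment estimates of the
# variance components, closed-form shrinkage toward the fixed slope.
two_stage_growth_fit <- function(d, biomarker_id, age_center) {
  by_subj <- split(d, d$subject_id)
  subjects <- names(by_subj)
  ols <- rep(NA_real_, length(subjects))
  sxx <- rep(NA_real_, length(subjects))
  rss <- 0
  rdf <- 0
  for (i in seq_along(by_subj)) {
    s <- by_subj[[i]]
    if (length(unique(s$age_c)) < 2) next
    xc <- s$age_c - mean(s$age_c)
    b <- sum(xc * s$value) / sum(xc^2)
    a <- mean(s$value) - b * mean(s$age_c)
    ols[i] <- b
    sxx[i] <- sum(xc^2)
    rss <- rss + sum((s$value - a - b * s$age_c)^2)
    rdf <- rdf + nrow(s) - 2
  }
  est <- !is.na(ols)
  if (!any(est)) stop_fit(sprintf("no subject has >= 2 distinct visit ages for '%s'", biomarker_id))
  sigma2 <- if (rdf > 0) rss / rdf else 0
  fixed_slope <- mean(ols[est])
  tau2 <- max(0, var(ols[est]) - sigma2 * mean(1 / sxx[est]))
  lambda <- rep(0, length(subjects))
  denom <- tau2 + sigma2 / sxx[est]
  lambda[est] <- ifelse(denom > 0, tau2 / denom, 1)
  slopes <- fixed_slope + lambda * (ifelse(est, ols, fixed_slope) - fixed_slope)
  names(slopes) <- subjects
  fixed_intercept <- mean(d$value) - fixed_slope * mean(d$age_c)
  new_growth_fit(biomarker_id, fixed_intercept, fixed_slope,
                 slopes[sort(subjects)],
                 c(intercept = NA_real_, slope = tau2, residual = sigma2),
                 age_center, "two-stage")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("<growth_model_fit> %s | fixed slope %.4f | %d subjects | method: %s\n",
              x$biomarker_id, x$fixed_slope, x$n_subjects, x$method))
  invisible(x)
}

#' Composite per-biomarker slopes into Pace of Aging scores
#'
#' Sums each subject's per-biomarker BLUP slopes and divides by the cohort
#' mean of the raw composite so the scored cohort has mean exactly 1 — one
#' "biological year per chronological year" on average. Subjects missing a
#' biomarker's slope receive the cohort mean slope for that biomarker
#' (imputations are counted); subjects missing more than half the
#' biomarkers are excluded from scaling and flagged. A non-positive cohort
#' mean composite raises an error, since it almost always signals
#' misconfigured biomarker orientations.
#'
#' @param fits list of [fit_growth_model()] results (one per biomarker).
#' @return An object of class `pace_scores`: a data.frame with columns
#'   `subject_id`, `pace`, `raw_composite`, `n_biomarkers_observed`, with
#'   attributes `scaling_constant`, `n_imputed`, `n_biomarkers` and
#'   `excluded_subjects`.
#' @export
compute_pace <- function(fits) {
  if (!length(fits)) stop_data("compute_pace needs at least one growth-model fit")
  if (!all(vapply(fits, inherits, logical(1), "growth_model_fit"))) {
    stop_data("fits must all be growth_model_fit objects")
  }
  subjects <- sort(unique(unlist(lapply(fits, function(f) names(f$slopes)))))
  nb <- length(fits)
  slopes <- matrix(NA_real_, length(subjects), nb,
                   dimnames = list(subjects, vapply(fits, `[[`, "", "biomarker_id")))
  for (j in seq_len(nb)) {
    slopes[names(fits[[j]]$slopes), j] <- fits[[j]]$slopes
  }
  n_obs <- rowSums(!is.na(slopes))
  excluded <- subjects[n_obs < nb / 2]
  keep <- setdiff(subjects, excluded)
  slopes <- slopes[keep, , drop = FALSE]
  n_imputed <- sum(is.na(slopes))
  if (n_imputed) {
    col_means <- colMeans(slopes, na.rm = TRUE)
    for (j in seq_len(nb)) {
      miss <- is.na(slopes[, j])
      slopes[miss, j] <- col_means[j]
    }
  }
  raw <- rowSums(slopes)
  scale_const <- mean(raw)
  if (!is.finite(scale_const) || scale_const <= 0) {
    stop_data(sprintf(
      "cohort mean raw composite is %.4g (must be > 0); check biomarker orientations",
      scale_const))
  }
  out <- data.frame(subject_id = keep,
                    pace = raw / scale_const,
                    raw_composite = raw,
                    n_biomarkers_observed = n_obs[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("pace_scores", "data.frame"),
            scaling_constant = scale_const, n_imputed = n_imputed,
            n_biomarkers = nb, excluded_subjects = excluded)
}

#' Pace of Aging from a raw biomarker panel
#'
#' Convenience pipeline: [standardize_panel()], then [fit_growth_model()]
#' for every biomarker in the metadata, then [compute_pace()].
#'
#' @inheritParams standardize_panel
#' @param min_subjects passed to [fit_growth_model()].
#' @param method passed to [fit_growth_model()].
#' @return A `pace_scores` object (see [compute_pace()]); the per-biomarker
#'   fits are attached as attribute `fits`.
#' @export
pace_of_aging <- function(panel, min_subjects = 10,
                          method = c("auto", "two-stage")) {
  method <- match.arg(method)
  std <- standardize_panel(panel)
  biomarkers <- unique(std$data$biomarker_id)
  fits <- lapply(biomarkers,
                 function(b) fit_growth_model(std, b, min_subjects, method))
  scores <- compute_pace(fits)
  attr(scores, "fits") <- fits
  scores
}
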