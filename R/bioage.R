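# Physiology-based biological-age comparators and validation statistics:
# Klemera-Doubal biological age, the Phenotypic Age functional form,
# homeostatic dysregulation, age-acceleration residuals, Pearson r and
# Cohen's d with confidence intervals.

#' Fit a biomarker reference population
#'
#' Per-biomarker ordinary least-squares regressions of marker on age
#' (intercept q_j, slope k_j, residual SD s_j) for the Klemera-Doubal
#' estimator, plus a healthy-subset mean vector and covariance matrix for
#' homeostatic dysregulation. The healthy subset defaults to the youngest
#' age tertile of the training table.
#'
#' @param data data.frame with an age column and one column per biomarker.
#' @param markers biomarker column names.
#' @param age_col name of the age column.
#' @param healthy_fraction fraction of youngest subjects forming the
#'   healthy reference (default youngest tertile).
#' @param s_floor lower floor on residual SDs (guards the noise-free
#'   degenerate case).
#' @param dysregulation also fit the healthy-subset centroid and covariance
#'   (required by [homeostatic_dysregulation()]; set `FALSE` for a
#'   markers-only reference, e.g. deterministic toy data whose covariance
#'   is singular by construction).
#' @return An object of class `bioage_reference`: `markers` (data.frame
#'   biomarker/q/k/s), `center`, `cov`, `age_range`.
#' @export
fit_bioage_reference <- function(data, markers, age_col = "age",
                                 healthy_fraction = 1 / 3, s_floor = 1e-8,
                                 dysregulation = TRUE) {
  data <- as.data.frame(data)
  if (!age_col %in% names(data)) stop_data(sprintf("age column '%s' not found", age_col))
  missing <- setdiff(markers, names(data))
  if (length(missing)) {
    stop_data(sprintf("markers missing from data: %s", paste(missing, collapse = ", ")))
  }
  age <- data[[age_col]]
  if (var(age) <= 0) stop_data("reference ages must vary")

  fits <- lapply(markers, function(mk) {
    f <- lm(data[[mk]] ~ age)
    s <- sqrt(sum(resid(f)^2) / f$df.residual)
    data.frame(biomarker = mk, q = unname(coef(f)[1]), k = unname(coef(f)[2]),
               s = max(s, s_floor), stringsAsFactors = FALSE)
  })
  ref_tab <- do.call(rbind, fits)

  center <- NULL
  covm <- NULL
  if (dysregulation) {
    healthy <- data[age <= quantile(age, healthy_fraction), markers, drop = FALSE]
    center <- colMeans(healthy)
    covm <- stats::cov(healthy)
    ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
    ok <- min(ev) > 1e-10 * max(abs(ev), 1e-300)
    if (!ok) {
      stop_data("healthy-reference covariance is not positive definite; consider removing collinear or constant markers")
    }
  }
  structure(list(markers = ref_tab, center = center, cov = covm,
                 age_range = range(age)),
            class = "bioage_reference")
}

#' Klemera-Doubal biological age
#'
#' Precision-weighted combination of inverse biomarker-on-age regressions:
#' `BA = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2`. With
#' `augmented = TRUE`, chronological age enters as an additional
#' pseudo-marker with SD `s_ba`:
#' `BA = (sum_j (x_j - q_j) k_j / s_j^2 + age / s_ba^2) /
#'       (sum_j k_j^2 / s_j^2 + 1 / s_ba^2)`.
#'
#' @param x named biomarker vector, or a subjects x markers matrix /
#'   data.frame with marker columns.
#' @param ref a [fit_bioage_reference()] result.
#' @param augmented include chronological age as an extra term.
#' @param age chronological ages (required when `augmented = TRUE`).
#' @param s_ba SD assigned to chronological age in the augmented variant.
#' @return Biological age(s) in years.
#' @export
kdm_biological_age <- function(x, ref, augmented = FALSE, age = NULL, s_ba = NULL) {
  stopifnot(inherits(ref, "bioage_reference"))
  x <- as_marker_matrix(x, ref$markers$biomarker)
  q <- ref$markers$q
  k <- ref$markers$k
  s2 <- ref$markers$s^2
  if (all(k == 0)) stop_data("all biomarker-age slopes are zero; biological age is undefined")
  num <- as.numeric(sweep(x, 2, q) %*% (k / s2))
  den <- sum(k^2 / s2)
  if (augmented) {
    if (is.null(age) || is.null(s_ba)) {
      stop_config("augmented KDM needs chronological age and s_ba")
    }
    num <- num + age / s_ba^2
    den <- den + 1 / s_ba^2
  }
  num / den
}

#' Phenotypic Age configuration
#'
#' Bundles the linear mortality-risk coefficients and Gompertz constants
#' used by [phenotypic_age()]. Published coefficient sets (e.g. Levine's)
#' can be supplied here as data; the package does not hard-code them.
#'
#' @param coef named numeric vector: `(Intercept)`, one entry per marker,
#'   and optionally `age` (coefficient on chronological age).
#' @param gamma Gompertz shape parameter (per year).
#' @param horizon mortality-risk horizon in years.
#' @param age_intercept,age_slope the age-only calibration: the linear
#'   predictor expected at chronological age a is
#'   `age_intercept + age_slope * a`, through which risk is inverted back
#'   to years.
#' @return An object of class `pheno_config`.
#' @export
pheno_config <- function(coef, gamma, horizon, age_intercept, age_slope) {
  vals <- c(coef, gamma, horizon, age_intercept, age_slope)
  if (!all(is.finite(vals))) stop_config("Phenotypic Age constants must be finite")
  if (gamma <= 0 || horizon <= 0) stop_config("gamma and horizon must be > 0")
  if (age_slope <= 0) stop_config("age_slope must be > 0 (risk must increase with age)")
  if (!"(Intercept)" %in% names(coef)) stop_config("coef must include an '(Intercept)' entry")
  structure(list(coef = coef, gamma = gamma, horizon = horizon,
                 age_intercept = age_intercept, age_slope = age_slope),
            class = "pheno_config")
}

#' Phenotypic Age
#'
#' Maps a biomarker profile (and optionally chronological age) through a
#' linear mortality-risk predictor xb, converts xb to a mortality risk over
#' the configured horizon via the Gompertz cumulative distribution,
#' `risk = 1 - exp(-exp(xb) * (exp(gamma * horizon) - 1) / gamma)`, and
#' inverts that risk through the age-only calibration to an age in years.
#' Strictly increasing in xb. Risks that underflow to 0 or saturate at 1
#' are clamped and flagged.
#'
#' @param x named biomarker vector or subjects x markers matrix.
#' @param pheno a [pheno_config()].
#' @param age chronological age(s); required when the coefficient set
#'   includes an `age` entry.
#' @return Phenotypic age(s) in years, with attribute `clamped` marking
#'   subjects whose risk was clamped.
#' @export
phenotypic_age <- function(x, pheno, age = NULL) {
  stopifnot(inherits(pheno, "pheno_config"))
  cf <- pheno$coef
  marker_names <- setdiff(names(cf), c("(Intercept)", "age"))
  x <- as_marker_matrix(x, marker_names)
  xb <- cf[["(Intercept)"]] + as.numeric(x %*% cf[marker_names])
  if ("age" %in% names(cf)) {
    if (is.null(age)) stop_config("this coefficient set includes age; supply chronological ages")
    xb <- xb + cf[["age"]] * age
  }
  g <- pheno$gamma
  cumhaz_scale <- (exp(g * pheno$horizon) - 1) / g
  risk <- 1 - exp(-exp(xb) * cumhaz_scale)
  eps <- 1e-300
  clamped <- risk <= eps | risk >= 1 - 1e-16
  risk <- pmin(pmax(risk, eps), 1 - 1e-16)
  pa <- (log(g * (-log1p(-risk)) / (exp(g * pheno$horizon) - 1)) - pheno$age_intercept) /
    pheno$age_slope
  # where risk was clamped, fall back to the analytically equivalent
  # inversion in xb (the Gompertz round trip is the identity in xb)
  pa[clamped] <- (xb[clamped] - pheno$age_intercept) / pheno$age_slope
  attr(pa, "clamped") <- clamped
  pa
}

#' Homeostatic dysregulation
#'
#' `log(1 + d)` where d is the Mahalanobis distance of the biomarker
#' profile from the healthy reference centroid under the reference
#' covariance: 0 at the centroid, and `log(1 + Euclidean distance)` under
#' an identity covariance.
#'
#' @param x named biomarker vector or subjects x markers matrix.
#' @param ref a [fit_bioage_reference()] result.
#' @return Dimensionless dysregulation value(s).
#' @export
homeostatic_dysregulation <- function(x, ref) {
  stopifnot(inherits(ref, "bioage_reference"))
  if (is.null(ref$cov)) {
    stop_data("reference was fit without the dysregulation covariance; refit with dysregulation = TRUE")
  }
  x <- as_marker_matrix(x, names(ref$center))
  d2 <- mahalanobis(x, ref$center, ref$cov)
  log(1 + sqrt(pmax(0, d2)))
}

as_marker_matrix <- function(x, marker_names) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (!is.null(names(x))) {
      missing <- setdiff(marker_names, names(x))
      if (length(missing)) {
        stop_data(sprintf("marker(s) missing from input: %s", paste(missing, collapse = ", ")))
      }
      x <- x[marker_names]
    } else if (length(x) != length(marker_names)) {
      stop_data(sprintf("expected %d markers, got %d values", length(marker_names), length(x)))
    }
    x <- matrix(x, nrow = 1, dimnames = list(NULL, marker_names))
  } else {
    if (!is.null(colnames(x))) {
      missing <- setdiff(marker_names, colnames(x))
      if (length(missing)) {
        stop_data(sprintf("marker column(s) missing: %s", paste(missing, collapse = ", ")))
      }
      x <- x[, marker_names, drop = FALSE]
    } else if (ncol(x) != length(marker_names)) {
      stop_data(sprintf("expected %d marker columns, got %d", length(marker_names), ncol(x)))
    }
  }
  x
}

#' Age-acceleration residuals
#'
#' Residuals from the OLS regression of a biological-age measure on
#' chronological age (with intercept); residuals sum to zero and are
#' invariant to adding any affine function of age to the measure.
#'
#' @param measure per-subject biological-age measure.
#' @param age chronological ages in years.
#' @return Residuals, one per subject.
#' @export
age_acceleration <- function(measure, age) {
  if (length(measure) != length(age)) stop_data("measure and age must have equal length")
  if (length(measure) < 3) stop_data("need >= 3 subjects")
  if (var(age) <= 0) stop_data("chronological age must vary")
  unname(resid(lm(measure ~ age)))
}

#' Cohen's d with confidence interval
#'
#' Standardized mean difference `(mean(x) - mean(y)) / pooled SD`, with the
#' Hedges-style large-sample standard error
#' `sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2 - 2)))` and a normal
#' interval.
#'
#' @param x,y numeric samples for the two groups.
#' @param conf_level confidence level.
#' @return A list: `d`, `lower`, `upper`, `n1`, `n2`.
#' @export
cohens_d <- function(x, y, conf_level = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_data("need >= 2 observations per group")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_data("pooled SD is zero; Cohen's d is undefined")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(d = d, lower = d - z * se, upper = d + z * se, n1 = n1, n2 = n2)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @param conf_level confidence level.
#' @return A list: `r`, `lower`, `upper`, `n`.
#' @export
pearson_cor <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop_data("need >= 3 complete pairs")
  ct <- stats::cor.test(x[ok], y[ok], conf.level = conf_level)
  list(r = unname(ct$estimate),
       lower = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
       upper = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
       n = sum(ok))
}

#' Default Klemera-Doubal biomarker metadata
#'
#' The 8-biomarker blood-chemistry/blood-pressure/lung-function panel
#' commonly used with the Klemera-Doubal and Phenotypic Age algorithms
#' (albumin, alkaline phosphatase, blood urea nitrogen, creatinine,
#' C-reactive protein, HbA1c, systolic blood pressure, FEV1), with the
#' conventional log-transform flags. All algorithms in this package are
#' panel-agnostic; this table is a convenience default for configuring
#' user or synthetic reference data.
#'
#' @return data.frame with columns `biomarker_id`, `name`,
#'   `log_transform`.
#' @export
kdm_default_biomarkers <- function() {
  data.frame(
    biomarker_id = c("albumin", "alp", "bun", "creatinine", "crp", "hba1c",
                     "sbp", "fev1"),
    name = c("Albumin", "Alkaline phosphatase", "Blood urea nitrogen",
             "Creatinine", "C-reactive protein", "HbA1c",
             "Systolic blood pressure", "FEV1"),
    log_transform = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
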