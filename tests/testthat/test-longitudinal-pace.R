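# Pace of Aging: baseline standardization, growth-model BLUPs, and the
# mean-one composite.

make_toy_panel <- function(values_by_subject, ages = c(26, 32), orientation = 1L,
                           biomarker = "bmA") {
  d <- do.call(rbind, lapply(names(values_by_subject), function(s) {
    data.frame(subject_id = s, visit_age = ages, biomarker_id = biomarker,
               value = values_by_subject[[s]], stringsAsFactors = FALSE)
  }))
  biomarker_panel(d, data.frame(biomarker_id = biomarker,
                                orientation = orientation, name = biomarker))
}

test_that("standardization z-scores against the baseline visit and applies orientation", {
  p <- make_toy_panel(list(a = c(8, 9), b = c(12, 15), c = c(14, 20)))
  # baseline (age 26) values: 8, 12, 14 -> mean 34/3, sd via sample SD
  m <- mean(c(8, 12, 14)); s <- sd(c(8, 12, 14))
  std <- standardize_panel(p)
  at_base <- std$data[std$data$visit_age == 26, ]
  expect_equal(at_base$value, (c(8, 12, 14) - m) / s)

  # baseline mean 10, SD 2 (values 8, 12, 10): a value of 14 maps to z = 2.0
  p2 <- make_toy_panel(list(a = c(8, 9), b = c(12, 14), c = c(10, 11)))
  std2 <- standardize_panel(p2)
  ref <- attr(std2, "standardization")
  expect_equal(ref$baseline_mean, 10)
  expect_equal(ref$baseline_sd, 2)
  expect_equal((14 - ref$baseline_mean) / ref$baseline_sd, 2.0)
  expect_equal(std2$data$value[std2$data$subject_id == "b" & std2$data$visit_age == 26],
               1.0)

  flipped <- make_toy_panel(list(a = c(8, 9), b = c(12, 15), c = c(14, 20)),
                            orientation = -1L)
  expect_equal(standardize_panel(flipped)$data$value, -std$data$value)
})

test_that("standardization is idempotent exactly when baseline is already standard", {
  p <- make_toy_panel(list(a = c(8, 9), b = c(12, 15), c = c(14, 20)))
  once <- standardize_panel(p)
  twice <- standardize_panel(once)
  expect_equal(twice$data$value, once$data$value, tolerance = 1e-12)

  # non-standard baseline: one pass changes values, so pre-standardized is required
  expect_false(isTRUE(all.equal(once$data$value, p$data$value)))
})

test_that("zero baseline variance raises an error naming the biomarker", {
  p <- make_toy_panel(list(a = c(5, 9), b = c(5, 15), c = c(5, 20)),
                      biomarker = "flatliner")
  err <- expect_error(standardize_panel(p), class = "mp_data_error")
  expect_match(conditionMessage(err), "flatliner")
})

test_that("noise-free growth models recover the planted slopes exactly", {
  sim <- simulate_longitudinal_cohort(40, residual_sd = 0, slope_dev_sd = 0, seed = 30)
  std <- standardize_panel(sim$panel)
  base_sd <- attr(std, "standardization")
  for (bm in c("bm01", "bm10")) {
    fit <- fit_growth_model(std, bm)
    s <- base_sd$baseline_sd[base_sd$biomarker_id == bm]
    want <- sim$truth$true_slopes[names(fit$slopes), bm] / s
    expect_lt(max(abs(fit$slopes - want)), 1e-6)
    expect_identical(fit$method, "two-stage")  # degenerate residual variance
  }
})

test_that("balanced-design BLUPs equal the closed-form shrinkage estimator", {
  sim <- simulate_longitudinal_cohort(150, seed = 31)
  std <- standardize_panel(sim$panel)
  fit <- fit_growth_model(std, "bm05")
  expect_identical(fit$method, "lmm")

  d <- std$data[std$data$biomarker_id == "bm05", ]
  d$age_c <- d$visit_age - mean(d$visit_age)
  sxx <- sum((unique(d$age_c))^2)  # balanced: same for every subject
  ols <- vapply(split(d, d$subject_id), function(s) ols_slope(s$age_c, s$value),
                numeric(1))
  lambda <- fit$varcomp[["slope"]] /
    (fit$varcomp[["slope"]] + fit$varcomp[["residual"]] / sxx)
  closed <- fit$fixed_slope + lambda * (ols[names(fit$slopes)] - fit$fixed_slope)
  expect_lt(max(abs(fit$slopes - closed)), 1e-3)
})

test_that("constant trajectories yield zero slopes and single-visit subjects shrink to the fixed slope", {
  d <- expand.grid(subject_id = sprintf("s%02d", 1:12), visit_age = c(26, 32, 38),
                   stringsAsFactors = FALSE)
  d$biomarker_id <- "bmA"; d$value <- 1
  p <- biomarker_panel(d, data.frame(biomarker_id = "bmA", orientation = 1L,
                                     name = "bmA"))
  fit <- fit_growth_model(p, "bmA")
  expect_true(all(fit$slopes == 0))
  expect_equal(fit$fixed_slope, 0)

  sim <- simulate_longitudinal_cohort(40, seed = 32)
  d2 <- sim$panel$data[sim$panel$data$biomarker_id == "bm01", ]
  # subject S0001 keeps only the first visit
  d2 <- d2[!(d2$subject_id == "S0001" & d2$visit_age > 26), ]
  p2 <- biomarker_panel(d2, data.frame(biomarker_id = "bm01", orientation = 1L,
                                       name = "bm01"))
  fit2 <- fit_growth_model(p2, "bm01")
  expect_true("S0001" %in% names(fit2$slopes))
  # fully shrunken: a single visit carries no slope information
  others <- fit2$slopes[names(fit2$slopes) != "S0001"]
  expect_lte(abs(fit2$slopes[["S0001"]] - fit2$fixed_slope),
             max(abs(others - fit2$fixed_slope)))

  expect_error(fit_growth_model(p2, "absent"), class = "mp_data_error")
  expect_error(fit_growth_model(p2, "bm01", min_subjects = 1000),
               class = "mp_data_error")
})

test_that("the composite is scaled to cohort mean exactly 1 and preserves ratios", {
  mk_fit <- function(slopes) {
    new_fit <- getFromNamespace("new_growth_fit", "methylpace")
    new_fit("bmX", 0, mean(slopes), slopes,
            c(intercept = 0, slope = 0, residual = 0), 35, "lmm")
  }
  # identical positive slopes -> every pace exactly 1
  f <- mk_fit(setNames(rep(0.4, 5), paste0("s", 1:5)))
  expect_true(all(compute_pace(list(f))$pace == 1))

  # raw composites (0.5, 1.0, 1.5) already have mean 1 -> pace unchanged
  f2 <- mk_fit(setNames(c(0.5, 1.0, 1.5), c("a", "b", "c")))
  ps <- compute_pace(list(f2))
  expect_equal(setNames(ps$pace, ps$subject_id), c(a = 0.5, b = 1.0, c = 1.5))
  expect_lt(abs(mean(ps$pace) - 1), 1e-10)

  # negative-mean composite flags an orientation problem
  f3 <- mk_fit(setNames(c(-0.5, -1), c("a", "b")))
  expect_error(compute_pace(list(f3)), class = "mp_data_error")
  expect_error(compute_pace(list()), class = "mp_data_error")
})

test_that("missing per-biomarker slopes are mean-imputed and mostly-missing subjects excluded", {
  new_fit <- getFromNamespace("new_growth_fit", "methylpace")
  mk <- function(id, slopes) new_fit(id, 0, mean(slopes), slopes,
                                     c(intercept = 0, slope = 0, residual = 0),
                                     35, "lmm")
  fits <- list(
    mk("b1", setNames(c(0.1, 0.2, 0.3), c("a", "b", "c"))),
    mk("b2", setNames(c(0.2, 0.4), c("a", "b"))),          # c missing -> imputed
    mk("b3", setNames(c(0.3, 0.1, 0.2), c("a", "b", "c")))
  )
  ps <- compute_pace(fits)
  expect_equal(attr(ps, "n_imputed"), 1L)
  raw_c <- 0.3 + mean(c(0.2, 0.4)) + 0.2
  expect_equal(ps$raw_composite[ps$subject_id == "c"], raw_c)

  # subject d observed for only 1 of 3 biomarkers -> excluded and flagged
  fits2 <- c(fits, list(mk("b4", setNames(c(0.1, 0.1, 0.1, 9), c("a", "b", "c", "d")))))
  ps2 <- compute_pace(fits2)
  expect_identical(attr(ps2, "excluded_subjects"), "d")
  expect_false("d" %in% ps2$subject_id)
})

test_that("pace is invariant to biomarker rescaling and faithful to the latent order", {
  sim <- simulate_longitudinal_cohort(60, seed = 33)
  scaled <- sim$panel
  rows <- scaled$data$biomarker_id == "bm03"
  scaled$data$value[rows] <- scaled$data$value[rows] * 37.5

  # standardization absorbs the rescaling essentially exactly (this is the
  # mechanism of the invariance)
  s1 <- standardize_panel(sim$panel)
  s2 <- standardize_panel(scaled)
  expect_lt(max(abs(s1$data$value - s2$data$value)), 1e-12)

  # closed-form estimator path: pace invariant to well below 1e-8
  t1 <- pace_of_aging(sim$panel, method = "two-stage")
  t2 <- pace_of_aging(scaled, method = "two-stage")
  expect_lt(max(abs(t1$pace - t2$pace)), 1e-8)

  # default ML path: invariant up to optimizer reproducibility (the
  # likelihood is flat near the slope-variance boundary, so ulp-level input
  # changes move the optimum stopping point by ~1e-6)
  ps1 <- pace_of_aging(sim$panel)
  ps2 <- pace_of_aging(scaled)
  expect_lt(max(abs(ps1$pace - ps2$pace)), 1e-4)

  nf <- simulate_longitudinal_cohort(50, residual_sd = 0, slope_dev_sd = 0, seed = 34)
  psn <- pace_of_aging(nf$panel)
  expect_equal(cor(psn$pace, nf$truth$latent_pace[psn$subject_id],
                   method = "spearman"), 1)
})

test_that("default cohorts recover the latent pace with r >= 0.8", {
  rs <- vapply(1:5, function(s) {
    sim <- simulate_longitudinal_cohort(500, seed = 500 + s)
    ps <- pace_of_aging(sim$panel)
    cor(ps$pace, sim$truth$latent_pace[ps$subject_id])
  }, numeric(1))
  expect_true(all(rs >= 0.8))
})
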