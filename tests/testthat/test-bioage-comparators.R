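# Physiology-based comparators: reference fitting, the three biological-age
# algorithms, age-acceleration residuals, and effect sizes.

make_ref_data <- function(n = 300, seed = 80, noise = 1) {
  withr::with_seed(seed, {
    age <- runif(n, 25, 75)
    data.frame(age = age,
               m1 = 5 + 0.4 * age + rnorm(n, 0, noise),
               m2 = 100 - 0.8 * age + rnorm(n, 0, 2 * noise),
               m3 = 0.2 * age + rnorm(n, 0, 0.5 * noise))
  })
}

test_that("reference fitting recovers the marker-age regressions", {
  d <- make_ref_data(noise = 0)  # noise-free: exact coefficients, floored SD
  # deterministic markers make the covariance singular, so fit markers only
  ref <- fit_bioage_reference(d, c("m1", "m2", "m3"), dysregulation = FALSE)
  expect_equal(ref$markers$q, c(5, 100, 0), tolerance = 1e-8)
  expect_equal(ref$markers$k, c(0.4, -0.8, 0.2), tolerance = 1e-8)
  expect_true(all(ref$markers$s >= 1e-8))

  # subject order is irrelevant
  dn <- make_ref_data()
  refn <- fit_bioage_reference(dn, c("m1", "m2", "m3"))
  perm <- withr::with_seed(81, sample(nrow(dn)))
  ref2 <- fit_bioage_reference(dn[perm, ], c("m1", "m2", "m3"))
  expect_equal(ref2$markers, refn$markers, tolerance = 1e-10)
  expect_equal(ref2$center, refn$center, tolerance = 1e-10)

  # one biomarker -> 1x1 covariance
  ref1 <- fit_bioage_reference(make_ref_data(), "m1")
  expect_identical(dim(ref1$cov), c(1L, 1L))

  # collinear markers break the covariance
  d$dup <- d$m1
  expect_error(fit_bioage_reference(d, c("m1", "dup")), class = "mp_data_error")
})

test_that("KDM biological age inverts the reference regressions", {
  d <- make_ref_data()
  ref <- fit_bioage_reference(d, c("m1", "m2", "m3"))
  q <- ref$markers$q; k <- ref$markers$k

  # on-the-line identity: x_j = q_j + k_j * a -> BA = a exactly
  for (a in c(30, 47.5, 70)) {
    x <- setNames(q + k * a, ref$markers$biomarker)
    expect_equal(kdm_biological_age(x, ref), a, tolerance = 1e-10)
  }

  # single biomarker: BA = (x - q) / k
  ref1 <- fit_bioage_reference(d, "m1")
  x1 <- setNames(12, "m1")
  expect_equal(kdm_biological_age(x1, ref1),
               (12 - ref1$markers$q) / ref1$markers$k, tolerance = 1e-10)

  # two-biomarker hand toy: q = (0,10), k = (1,2), s = (1,1), x = (30,74)
  toy <- structure(list(markers = data.frame(biomarker = c("a", "b"),
                                             q = c(0, 10), k = c(1, 2),
                                             s = c(1, 1)),
                        center = c(a = 0, b = 0), cov = diag(2),
                        age_range = c(20, 80)),
                   class = "bioage_reference")
  expect_equal(kdm_biological_age(c(a = 30, b = 74), toy),
               (30 * 1 + 64 * 2) / (1 + 4))
  expect_equal(kdm_biological_age(c(a = 30, b = 74), toy), 31.6)

  # augmented variant pulls the estimate toward chronological age
  ba_plain <- kdm_biological_age(c(a = 30, b = 74), toy)
  ba_aug <- kdm_biological_age(c(a = 30, b = 74), toy, augmented = TRUE,
                               age = 50, s_ba = 5)
  expect_true(abs(ba_aug - 50) < abs(ba_plain - 50))

  zero_k <- toy; zero_k$markers$k <- c(0, 0)
  expect_error(kdm_biological_age(c(a = 1, b = 2), zero_k), class = "mp_data_error")
})

test_that("KDM applied to the reference population tracks chronological age", {
  d <- make_ref_data(n = 1000, seed = 82)
  ref <- fit_bioage_reference(d, c("m1", "m2", "m3"))
  ba <- kdm_biological_age(d[, c("m1", "m2", "m3")], ref)
  slope <- unname(coef(lm(ba ~ d$age))[2])
  expect_lt(abs(slope - 1), 0.1)
})

test_that("Phenotypic Age is calibrated, monotone, and matches numerical inversion", {
  cfg <- pheno_config(coef = c("(Intercept)" = -10, m1 = 0.05, age = 0.08),
                      gamma = 0.09, horizon = 10,
                      age_intercept = -9, age_slope = 0.1)

  # calibration fixed point: a profile whose linear predictor equals the
  # age-model value at age a maps back to a
  for (a in c(30, 55, 80)) {
    xb_target <- cfg$age_intercept + cfg$age_slope * a
    m1 <- (xb_target + 10 - 0.08 * a) / 0.05
    expect_equal(phenotypic_age(c(m1 = m1), cfg, age = a), a, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  # strictly increasing in the linear predictor
  pa <- phenotypic_age(cbind(m1 = c(10, 20, 30)), cfg, age = rep(50, 3))
  expect_true(all(diff(pa) > 0))

  # brute-force inversion oracle: solve risk(age) = risk(xb) numerically
  risk_of <- function(xb) 1 - exp(-exp(xb) * (exp(cfg$gamma * cfg$horizon) - 1) / cfg$gamma)
  for (m1 in c(5, 40)) {
    xb <- -10 + 0.05 * m1 + 0.08 * 50
    target <- risk_of(xb)
    inv <- stats::uniroot(function(a) {
      risk_of(cfg$age_intercept + cfg$age_slope * a) - target
    }, c(-500, 500), tol = 1e-12)$root
    expect_equal(phenotypic_age(c(m1 = m1), cfg, age = 50), inv,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }

  # extreme profiles clamp but stay finite and ordered
  pa_ext <- phenotypic_age(cbind(m1 = c(-1e5, 1e5)), cfg, age = c(50, 50))
  expect_true(all(is.finite(pa_ext)))
  expect_true(attr(pa_ext, "clamped")[2])
  expect_lt(pa_ext[1], pa_ext[2])

  expect_error(pheno_config(coef = c(m1 = 1), gamma = 0.1, horizon = 10,
                            age_intercept = 0, age_slope = 0.1),
               class = "mp_config_error")
})

test_that("homeostatic dysregulation is a log Mahalanobis distance from health", {
  d <- make_ref_data()
  ref <- fit_bioage_reference(d, c("m1", "m2", "m3"))
  expect_equal(homeostatic_dysregulation(ref$center, ref), 0)

  # identity covariance reduces to log(1 + Euclidean distance)
  iden <- structure(list(markers = ref$markers,
                         center = c(m1 = 0, m2 = 0, m3 = 0),
                         cov = diag(3), age_range = c(25, 75)),
                    class = "bioage_reference")
  x <- c(m1 = 3, m2 = 4, m3 = 0)
  expect_equal(homeostatic_dysregulation(x, iden), log(1 + 5))

  # non-diagonal covariance: explicit quadratic form oracle
  S <- matrix(c(2, 0.5, 0.1, 0.5, 1.5, 0.2, 0.1, 0.2, 1), 3, 3)
  gen <- structure(list(markers = ref$markers,
                        center = c(m1 = 1, m2 = 2, m3 = 3), cov = S,
                        age_range = c(25, 75)),
                   class = "bioage_reference")
  x2 <- c(m1 = 2.5, m2 = 1, m3 = 4)
  dlt <- x2 - gen$center
  expect_equal(homeostatic_dysregulation(x2, gen),
               log(1 + sqrt(drop(t(dlt) %*% solve(S) %*% dlt))),
               tolerance = 1e-8)

  expect_error(homeostatic_dysregulation(c(m1 = 1), ref), class = "mp_data_error")
})

test_that("dysregulation is invariant to affine marker rescaling after refit", {
  d <- make_ref_data()
  markers <- c("m1", "m2", "m3")
  ref <- fit_bioage_reference(d, markers)
  x <- c(m1 = 40, m2 = 50, m3 = 10)
  d2 <- d
  d2$m2 <- 3.7 * d$m2 - 12
  ref2 <- fit_bioage_reference(d2, markers)
  x2 <- x; x2[["m2"]] <- 3.7 * x[["m2"]] - 12
  expect_equal(homeostatic_dysregulation(x2, ref2),
               homeostatic_dysregulation(x, ref), tolerance = 1e-8)
})

test_that("age-acceleration residuals behave as an OLS projection", {
  age <- c(30, 40, 50, 60, 70)
  expect_equal(age_acceleration(2 * age + 5, age), rep(0, 5), tolerance = 1e-12)

  measure <- withr::with_seed(83, rnorm(200))
  ages <- withr::with_seed(84, runif(200, 30, 70))
  res <- age_acceleration(measure, ages)
  expect_lt(abs(sum(res)), 1e-8)
  expect_equal(res, unname(resid(lm(measure ~ ages))), tolerance = 1e-12)

  # invariant to adding any affine function of age
  expect_equal(age_acceleration(measure + 3 * ages - 7, ages), res,
               tolerance = 1e-10)

  expect_error(age_acceleration(c(1, 2, 3), c(50, 50, 50)), class = "mp_data_error")
  expect_error(age_acceleration(c(1, 2), c(30, 40)), class = "mp_data_error")
})

test_that("effect sizes recover planted magnitudes", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x)$d, 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "mp_data_error")

  ds <- vapply(1:20, function(s) {
    withr::with_seed(3000 + s, cohens_d(rnorm(500, 0.74), rnorm(500, 0))$d)
  }, numeric(1))
  expect_true(all(abs(ds - 0.74) < 0.15))
  expect_lt(abs(mean(ds) - 0.74), 0.05)

  v <- 1:50
  expect_equal(pearson_cor(v, v)$r, 1)
  pc <- withr::with_seed(85, pearson_cor(rnorm(100), rnorm(100)))
  expect_true(pc$lower <= pc$r && pc$r <= pc$upper)

  expect_identical(nrow(kdm_default_biomarkers()), 8L)
})
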