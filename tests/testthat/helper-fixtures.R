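# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

# default-settings cohort used across modules
fx_cohort <- function() fixture("cohort", simulate_longitudinal_cohort(200, seed = 42))

# methylation matrix keyed to the cohort's latent pace
fx_methyl <- function() fixture("methyl", {
  pace <- fx_cohort()$truth$latent_pace
  simulate_methylation(pace, n_probes = 1000, n_causal = 40, seed = 43)
})

# a small trained model (train on first 150 samples)
fx_model <- function() fixture("model", {
  m <- fx_methyl()
  pace <- fx_cohort()$truth$latent_pace
  w <- train_elastic_net(m$betas[, 1:150], pace[colnames(m$betas)[1:150]], seed = 44)
  panel <- build_reference_panel(w, m$betas[, 1:150], panel_size = 1000, seed = 45)
  trained_model(w, panel)
})

# tiny hand-checkable reference panel
fx_panel5 <- function() {
  data.frame(probe_id = paste0("p", 1:5),
             reference_mean = c(0.2, 0.3, 0.4, 0.6, 0.8),
             is_algorithm_probe = TRUE,
             stringsAsFactors = FALSE)
}

# per-subject OLS slope: the independent oracle for growth-model tests
ols_slope <- function(ages, values) {
  xc <- ages - mean(ages)
  sum(xc * values) / sum(xc^2)
}

# large probe universe + synthetic 173-probe weight table, shared by the
# published-structure and rank-invariance checks
fx_big <- function() fixture("big", {
  pace <- stats::setNames(seq(0.6, 1.4, length.out = 40), sprintf("u%02d", 1:40))
  sim <- simulate_methylation(pace, n_probes = 21000, n_causal = 0, seed = 46)
  wt <- withr::with_seed(47, {
    probes <- sample(rownames(sim$betas), 173)
    weight_table(1.2, stats::setNames(rnorm(173, 0, 0.5), probes),
                 provenance = "synthetic 173-probe weight set")
  })
  list(betas = sim$betas, weights = wt)
})
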