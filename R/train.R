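# Distilling a Pace of Aging phenotype into a CpG scoring algorithm:
# reliability-restricted elastic net, frozen reference normalization panel,
# and a lossless on-disk model format.

#' Construct a CpG weight table
#'
#' @param intercept score-units intercept.
#' @param weights named numeric vector of per-probe weights (score units per
#'   normalized beta); zero weights are dropped.
#' @param alpha,lambda elastic-net mixing parameter and penalty at which the
#'   weights were obtained (NA when loaded from an external table).
#' @param provenance free-text training description.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(intercept, weights = numeric(0), alpha = NA_real_,
                         lambda = NA_real_, provenance = "") {
  weights <- weights[weights != 0]
  if (length(weights) && is.null(names(weights))) {
    stop_data("weights must be named by probe ID")
  }
  if (anyDuplicated(names(weights))) stop_data("duplicate probe IDs in weights")
  structure(list(intercept = unname(intercept), weights = weights,
                 alpha = alpha, lambda = lambda, provenance = provenance),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d weighted probes | intercept %.4g | alpha = %s, lambda = %s\n",
              length(x$weights), x$intercept,
              format(x$alpha), format(x$lambda)))
  invisible(x)
}

#' Train an elastic-net CpG scoring algorithm
#'
#' Restricts predictors to the reliable probe set, fits an elastic net of
#' the pace phenotype on beta values (predictors standardized internally for
#' fitting; coefficients returned on the original beta scale), and keeps the
#' probes with nonzero weight at the selected penalty. When `lambda` is a
#' grid (or NULL for the default glmnet path), the penalty is chosen at the
#' minimum mean cross-validated squared error with fold assignment
#' deterministic given `seed`; a single `lambda` value is fit directly.
#'
#' @param betas probes x samples beta matrix.
#' @param pace a `pace_scores` object or named numeric vector, aligned to
#'   the matrix's sample columns.
#' @param reliable probe IDs allowed as predictors (e.g. from
#'   [filter_probes()]); defaults to all probes.
#' @param alpha elastic-net mixing parameter in \[0,1\] (0.5 by default:
#'   equal L1/L2 mixing).
#' @param lambda NULL (glmnet's path), a grid, or a single penalty value.
#' @param cv_folds number of cross-validation folds.
#' @param seed RNG seed controlling fold assignment.
#' @param lambda_rule `"min"` (penalty at minimum mean CV error, the
#'   default) or `"1se"` (largest penalty within one standard error of the
#'   minimum; sparser, near-zero false-discovery selection at some cost in
#'   sensitivity).
#' @return A [weight_table()] with the chosen `lambda` recorded.
#' @export
train_elastic_net <- function(betas, pace, reliable = rownames(betas),
                              alpha = 0.5, lambda = NULL, cv_folds = 10,
                              seed = NULL, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is.matrix(betas)) stop_data("betas must be a probes x samples matrix")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop_config("alpha must lie in [0,1]")
  if (!is_count(cv_folds) || cv_folds < 2) stop_config("cv_folds must be an integer >= 2")
  y <- as_pace_vector(pace)
  if (is.null(names(y))) {
    if (length(y) != ncol(betas)) stop_data("unnamed pace vector must match sample count")
    names(y) <- colnames(betas)
  }
  common <- intersect(colnames(betas), names(y))
  # every beta column needs a phenotype; the phenotype may cover more
  # subjects than the training matrix
  if (length(common) < ncol(betas)) {
    stop_data(sprintf("samples of betas and pace are misaligned: %d in common, %d betas, %d pace",
                      length(common), ncol(betas), length(y)))
  }
  reliable <- intersect(reliable, rownames(betas))
  if (!length(reliable)) stop_data("reliable probe set is empty after intersection with the beta matrix")
  if (length(common) < cv_folds) stop_data("need at least cv_folds samples")

  x <- t(betas[reliable, common, drop = FALSE])
  y <- y[common]
  if (var(y) < .Machine$double.eps) {
    return(weight_table(y[[1]], alpha = alpha, lambda = NA_real_,
                        provenance = "constant response; null model"))
  }

  # glmnet requires >= 2 predictor columns; pad a single predictor with a
  # constant dummy column (zero variance -> zero coefficient) and drop it
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `..pad..` = 0)

  if (!is.null(lambda) && length(lambda) == 1) {
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda, standardize = TRUE,
                          thresh = 1e-12)
    chosen <- lambda
    cf <- coef(fit, s = lambda, exact = FALSE)
  } else {
    foldid <- run_seeded(seed, function() sample(rep_len(seq_len(cv_folds), length(y))))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, lambda = lambda,
                            foldid = foldid, standardize = TRUE)
    chosen <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- coef(cv, s = chosen)
  }
  cf <- as.matrix(cf)[, 1]
  w <- cf[-1]
  if (padded) w <- w[names(w) != "..pad.."]
  weight_table(cf[["(Intercept)"]], w[w != 0], alpha = alpha, lambda = chosen,
               provenance = sprintf("elastic net on %d samples x %d reliable probes",
                                    length(y), length(reliable)))
}

as_pace_vector <- function(pace) {
  if (inherits(pace, "pace_scores")) {
    setNames(pace$pace, pace$subject_id)
  } else if (is.data.frame(pace) && all(c("subject_id", "pace") %in% names(pace))) {
    setNames(pace$pace, pace$subject_id)
  } else if (is.numeric(pace)) {
    pace
  } else {
    stop_data("pace must be a pace_scores object or a numeric vector")
  }
}

#' Build a frozen reference normalization panel
#'
#' The panel is the ordered union of the algorithm (weighted) probes and
#' background probes sampled without replacement from the rest of the probe
#' universe, stratified across deciles of the training-set mean beta so the
#' panel represents the underlying beta distribution (simple random sampling
#' available via `stratified = FALSE`). Each panel probe stores its
#' training-set mean beta as the reference value; the sorted vector of these
#' reference means is the target distribution for quantile normalization at
#' scoring time. Sampling happens once here — never at scoring time.
#'
#' @param weights a [weight_table()].
#' @param betas training probes x samples beta matrix (must cover the
#'   universe).
#' @param universe candidate probe IDs (defaults to all rows of `betas`).
#' @param panel_size total panel size (default 20000).
#' @param seed RNG seed for the background draw.
#' @param stratified stratify the background draw across deciles of mean
#'   beta (default) or sample uniformly.
#' @return A data.frame of class `reference_panel` with columns `probe_id`,
#'   `reference_mean`, `is_algorithm_probe`; attributes `seed` and
#'   `stratified`.
#' @export
build_reference_panel <- function(weights, betas, universe = rownames(betas),
                                  panel_size = 20000, seed = NULL,
                                  stratified = TRUE) {
  stopifnot(inherits(weights, "weight_table"))
  wprobes <- names(weights$weights)
  if (!all(wprobes %in% universe)) {
    stop_data(sprintf("%d weighted probes are missing from the probe universe",
                      sum(!wprobes %in% universe)))
  }
  if (!all(universe %in% rownames(betas))) {
    stop_data("the beta matrix must cover every universe probe (reference means are training means)")
  }
  if (length(universe) < panel_size) {
    stop_data(sprintf("probe universe (%d) is smaller than panel_size (%d)",
                      length(universe), panel_size))
  }
  if (panel_size < length(wprobes)) {
    stop_config("panel_size must be >= the number of weighted probes")
  }
  ref_means <- rowMeans(betas[universe, , drop = FALSE], na.rm = TRUE)
  names(ref_means) <- universe
  pool <- setdiff(universe, wprobes)
  n_bg <- panel_size - length(wprobes)

  bg <- if (n_bg == 0) character(0) else run_seeded(seed, function() {
    if (!stratified || length(pool) < 20) {
      sample(pool, n_bg)
    } else {
      sample_stratified_deciles(pool, ref_means[pool], n_bg)
    }
  })
  panel <- data.frame(
    probe_id = c(wprobes, bg),
    reference_mean = unname(ref_means[c(wprobes, bg)]),
    is_algorithm_probe = c(rep(TRUE, length(wprobes)), rep(FALSE, length(bg))),
    stringsAsFactors = FALSE
  )
  structure(panel, class = c("reference_panel", "data.frame"),
            seed = seed, stratified = stratified)
}

# Allocate the background draw proportionally across deciles of mean beta
# (largest-remainder rounding), then sample without replacement per decile.
sample_stratified_deciles <- function(pool, means, n_bg) {
  br <- unique(quantile(means, probs = 0:10 / 10, names = FALSE))
  bins <- cut(means, breaks = br, include.lowest = TRUE, labels = FALSE)
  sizes <- tabulate(bins, nbins = length(br) - 1)
  exact <- n_bg * sizes / length(pool)
  alloc <- floor(exact)
  rem <- n_bg - sum(alloc)
  if (rem > 0) {
    order_rem <- order(exact - alloc, decreasing = TRUE)
    alloc[order_rem[seq_len(rem)]] <- alloc[order_rem[seq_len(rem)]] + 1
  }
  # cap at bin size and push any spill into other bins with headroom
  spill <- sum(pmax(0, alloc - sizes))
  alloc <- pmin(alloc, sizes)
  while (spill > 0) {
    room <- which(alloc < sizes)
    take <- room[seq_len(min(spill, length(room)))]
    alloc[take] <- alloc[take] + 1
    spill <- spill - length(take)
  }
  unlist(lapply(which(alloc > 0), function(b) {
    in_bin <- pool[bins == b]
    if (alloc[b] >= length(in_bin)) in_bin else sample(in_bin, alloc[b])
  }), use.names = FALSE)
}

#' Bundle weights and panel into a trained model
#'
#' @param weights a [weight_table()].
#' @param panel a [build_reference_panel()] result containing every
#'   weighted probe.
#' @param version model format version tag.
#' @return An object of class `trained_model`.
#' @export
trained_model <- function(weights, panel, version = "1.0") {
  stopifnot(inherits(weights, "weight_table"))
  if (!all(c("probe_id", "reference_mean", "is_algorithm_probe") %in% names(panel))) {
    stop_data("panel must have probe_id, reference_mean and is_algorithm_probe columns")
  }
  missing <- setdiff(names(weights$weights), panel$probe_id)
  if (length(missing)) {
    stop_data(sprintf("panel is missing %d weighted probes (e.g. %s)",
                      length(missing), missing[1]))
  }
  if (any(!is.finite(panel$reference_mean)) ||
      any(panel$reference_mean < 0 | panel$reference_mean > 1)) {
    stop_data("panel reference means must lie in [0,1]")
  }
  if (anyDuplicated(panel$probe_id)) stop_data("duplicate probe IDs in panel")
  structure(list(weights = weights, panel = as.data.frame(panel), version = version),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model v%s> %d algorithm probes | %d-probe reference panel (%d background)\n",
              x$version, length(x$weights$weights), nrow(x$panel),
              sum(!x$panel$is_algorithm_probe)))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Save a trained model to a directory
#'
#' Writes `weights.csv` (probe_id, weight, with an `intercept` row),
#' `panel.csv` (probe_id, reference_mean, is_algorithm_probe) and
#' `model.json` (version, alpha, lambda, sizes). Numeric values are written
#' with round-trip precision so save/load is lossless.
#'
#' @param model a [trained_model()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_weight_table(model$weights, file.path(path, "weights.csv"))
  panel <- model$panel
  panel$is_algorithm_probe <- as.integer(panel$is_algorithm_probe)
  fwrite_full(panel, file.path(path, "panel.csv"))
  meta <- list(version = model$version,
               alpha = model$weights$alpha,
               lambda = model$weights$lambda,
               provenance = model$weights$provenance,
               n_algorithm_probes = length(model$weights$weights),
               panel_size = nrow(model$panel))
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a trained model from a directory
#'
#' Reconstructs and integrity-checks a model written by [save_model()]:
#' unknown format versions and weighted probes absent from the panel are
#' errors.
#'
#' @param path model directory.
#' @return A [trained_model()].
#' @export
load_model <- function(path) {
  for (f in c("weights.csv", "panel.csv", "model.json")) {
    if (!file.exists(file.path(path, f))) {
      stop_data(sprintf("model directory is missing %s", f))
    }
  }
  meta <- jsonlite::read_json(file.path(path, "model.json"), simplifyVector = TRUE)
  if (!identical(as.character(meta$version), MODEL_FORMAT_VERSION)) {
    stop_data(sprintf("unsupported model format version '%s' (expected %s)",
                      meta$version, MODEL_FORMAT_VERSION))
  }
  w <- read_weight_table(file.path(path, "weights.csv"))
  w$alpha <- meta$alpha %||% NA_real_
  w$lambda <- meta$lambda %||% NA_real_
  w$provenance <- meta$provenance %||% ""
  panel <- as.data.frame(data.table::fread(file.path(path, "panel.csv")))
  panel$is_algorithm_probe <- as.logical(panel$is_algorithm_probe)
  trained_model(w, panel, version = as.character(meta$version))
}
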