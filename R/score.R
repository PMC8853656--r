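# Applying a trained model to new beta matrices: panel alignment,
# per-sample quantile normalization against the frozen reference
# distribution, missingness gating, and the weighted-sum score.

#' Align a beta matrix to a reference panel
#'
#' Subsets and reorders the matrix to the panel's probe list; probes absent
#' from the matrix become missing rows. Per-sample fractions of algorithm
#' and panel probes present are attached for the missingness gate.
#'
#' @param m probes x samples beta matrix.
#' @param panel a reference panel (from [build_reference_panel()] or a
#'   [trained_model()]'s `$panel`).
#' @return The aligned matrix (panel probes x samples) with attributes
#'   `frac_panel_probes` and `frac_algo_probes` per sample.
#' @export
align_to_panel <- function(m, panel) {
  if (!is.matrix(m)) stop_data("m must be a probes x samples matrix")
  out <- matrix(NA_real_, nrow(panel), ncol(m),
                dimnames = list(panel$probe_id, colnames(m)))
  hit <- intersect(panel$probe_id, rownames(m))
  out[hit, ] <- m[hit, , drop = FALSE]
  algo <- panel$is_algorithm_probe
  attr(out, "frac_panel_probes") <- colMeans(!is.na(out))
  attr(out, "frac_algo_probes") <-
    if (any(algo)) colMeans(!is.na(out[algo, , drop = FALSE])) else rep(1, ncol(out))
  out
}

#' Quantile-normalize samples to the reference distribution
#'
#' Per sample, independently: missing values are first imputed with the
#' probe's reference mean (keeping the rank vector complete); each value is
#' then replaced by the reference target value at its within-sample rank,
#' where the target is the sorted vector of panel reference means. Ties
#' receive the mean of the tied target positions. Any strictly increasing
#' per-sample transform of the input leaves the output unchanged.
#'
#' @param m aligned beta matrix (rows must equal the panel's probe list).
#' @param panel the reference panel.
#' @return The normalized matrix; samples with all values missing are
#'   returned as all-`NA` columns and listed in attribute
#'   `unnormalizable_samples`.
#' @export
quantile_normalize_to_reference <- function(m, panel) {
  if (!identical(rownames(m), panel$probe_id)) {
    stop_data("matrix rows must equal the panel probe list; run align_to_panel() first")
  }
  target <- sort(panel$reference_mean)
  cs <- c(0, cumsum(target))
  ref <- panel$reference_mean
  out <- m
  dead <- character(0)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    miss <- is.na(x)
    if (all(miss)) {
      dead <- c(dead, colnames(m)[j] %||% as.character(j))
      next
    }
    x[miss] <- ref[miss]
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    out[, j] <- (cs[rmax + 1] - cs[rmin]) / (rmax - rmin + 1)
  }
  attr(out, "unnormalizable_samples") <- dead
  out
}

#' Score a beta matrix with a trained model
#'
#' Pipeline: align to the panel, refuse samples failing the missingness
#' gate (below `min_algo_frac` of algorithm probes or `min_panel_frac` of
#' panel probes present), quantile-normalize the remainder to the
#' reference distribution, and compute
#' `score = intercept + sum_j weight_j * normalized_beta_j`. Scoring is
#' fully deterministic — no randomness is used.
#'
#' @param m probes x samples beta matrix.
#' @param model a [trained_model()].
#' @param min_algo_frac minimum fraction of algorithm probes present.
#' @param min_panel_frac minimum fraction of panel probes present.
#' @return A data.frame of class `pace_score_result` with columns
#'   `sample_id`, `score`, `frac_algo_probes`, `frac_panel_probes`,
#'   `n_imputed`, `flag` (empty string for cleanly scored samples).
#' @export
score <- function(m, model, min_algo_frac = 0.8, min_panel_frac = 0.8) {
  stopifnot(inherits(model, "trained_model"))
  panel <- model$panel
  if (!length(intersect(rownames(m), panel$probe_id))) {
    stop_data("no overlap between the matrix probes and the model panel")
  }
  aligned <- align_to_panel(m, panel)
  frac_algo <- attr(aligned, "frac_algo_probes")
  frac_panel <- attr(aligned, "frac_panel_probes")
  refused <- frac_algo < min_algo_frac | frac_panel < min_panel_frac
  n_imputed <- colSums(is.na(aligned))

  scores <- rep(NA_real_, ncol(aligned))
  flags <- character(ncol(aligned))
  flags[refused] <- sprintf(
    "refused: %.1f%% algorithm probes, %.1f%% panel probes present",
    100 * frac_algo[refused], 100 * frac_panel[refused])
  if (any(!refused)) {
    norm <- quantile_normalize_to_reference(aligned[, !refused, drop = FALSE], panel)
    w <- model$weights$weights
    scores[!refused] <- model$weights$intercept +
      as.numeric(crossprod(norm[names(w), , drop = FALSE], w))
  }
  structure(data.frame(sample_id = colnames(m) %||% as.character(seq_len(ncol(m))),
                       score = scores,
                       frac_algo_probes = unname(frac_algo),
                       frac_panel_probes = unname(frac_panel),
                       n_imputed = unname(n_imputed),
                       flag = flags,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("pace_score_result", "data.frame"),
            model_version = model$version)
}

#' Score-level test-retest reliability
#'
#' ICC of scores across two replicate datasets, matched by sample ID and
#' delegated to [estimate_icc()].
#'
#' @param scores_a,scores_b [score()] results (or named numeric vectors)
#'   for the two replicate datasets.
#' @return An [estimate_icc()] result.
#' @export
score_replicate_reliability <- function(scores_a, scores_b) {
  a <- as_score_vector(scores_a)
  b <- as_score_vector(scores_b)
  common <- intersect(names(a), names(b))
  common <- common[!is.na(a[common]) & !is.na(b[common])]
  if (length(common) < 2) stop_data("need >= 2 scored replicate pairs")
  estimate_icc(cbind(a[common], b[common]))
}

as_score_vector <- function(s) {
  if (is.data.frame(s) && all(c("sample_id", "score") %in% names(s))) {
    setNames(s$score, s$sample_id)
  } else if (is.numeric(s) && !is.null(names(s))) {
    s
  } else {
    stop_data("scores must be a score() result or a named numeric vector")
  }
}
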