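# Test-retest reliability via one-way random-effects variance components
# (single measurement, absolute agreement): replicates are interchangeable
# aliquots, not raters.

#' Intraclass correlation from a sample x replicate matrix
#'
#' One-way random-effects ANOVA estimator. With samples i = 1..n and k_i
#' replicates each, the between- and within-sample mean squares give
#' sigma2_b = (MSB - MSW) / n0 (n0 the mean replicate count corrected for
#' imbalance) and ICC = sigma2_b / (sigma2_b + sigma2_w). Negative
#' between-sample variance estimates are truncated at 0 and flagged. The
#' confidence interval is the F-distribution interval for the one-way ICC.
#'
#' @param values numeric matrix with one row per sample and one column per
#'   replicate; `NA` marks missing replicates (unbalanced designs allowed).
#' @param conf_level confidence level for the interval.
#' @return An object of class `icc_estimate`: `icc`, `lower`, `upper`,
#'   `sigma2_between`, `sigma2_within`, `n_samples`, `mean_reps`,
#'   `truncated`.
#' @export
estimate_icc <- function(values, conf_level = 0.95) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_data("values must be numeric")
  if (any(is.infinite(values))) stop_data("values must be finite")
  k_i <- rowSums(!is.na(values))
  values <- values[k_i >= 1, , drop = FALSE]
  k_i <- k_i[k_i >= 1]
  n <- nrow(values)
  if (n < 2 || sum(k_i >= 2) < 2) {
    stop_data("need >= 2 samples, with >= 2 replicates for at least 2 samples")
  }
  N <- sum(k_i)
  means_i <- rowMeans(values, na.rm = TRUE)
  grand <- sum(values, na.rm = TRUE) / N
  ssb <- sum(k_i * (means_i - grand)^2)
  ssw <- sum((values - means_i)^2, na.rm = TRUE)
  if (ssb + ssw < .Machine$double.eps) {
    stop_data("all values are identical; ICC is undefined for zero total variance")
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  n0 <- (N - sum(k_i^2) / N) / (n - 1)
  sigma2_b <- (msb - msw) / n0
  truncated <- sigma2_b < 0
  sigma2_b <- max(0, sigma2_b)
  icc <- sigma2_b / (sigma2_b + msw)

  # Searle's F interval for the one-way ICC
  alpha <- 1 - conf_level
  if (msw > 0) {
    f <- msb / msw
    fl <- f / qf(1 - alpha / 2, n - 1, N - n)
    fu <- f * qf(1 - alpha / 2, N - n, n - 1)
    lower <- (fl - 1) / (fl + n0 - 1)
    upper <- (fu - 1) / (fu + n0 - 1)
  } else {
    lower <- upper <- 1
  }
  structure(list(icc = icc,
                 lower = max(0, min(1, lower)),
                 upper = max(0, min(1, upper)),
                 sigma2_between = sigma2_b,
                 sigma2_within = msw,
                 n_samples = n,
                 mean_reps = N / n,
                 truncated = truncated),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC = %.3f, 95%% CI [%.3f, %.3f] (n = %d samples, %.1f replicates/sample)\n",
              x$icc, x$lower, x$upper, x$n_samples, x$mean_reps))
  invisible(x)
}

#' Replicate design: which measurement columns belong to which sample
#'
#' @param sample_id character vector, one entry per measurement column.
#' @param replicate_column character vector of measurement column names.
#' @return A validated data.frame with columns `sample_id` and
#'   `replicate_column`.
#' @export
replicate_design <- function(sample_id, replicate_column) {
  if (length(sample_id) != length(replicate_column)) {
    stop_data("sample_id and replicate_column must have equal length")
  }
  if (anyDuplicated(replicate_column)) {
    stop_data("a replicate column is assigned to more than one sample")
  }
  data.frame(sample_id = as.character(sample_id),
             replicate_column = as.character(replicate_column),
             stringsAsFactors = FALSE)
}

#' Per-probe ICC table from replicate beta matrices
#'
#' Applies the one-way variance-components ICC independently to every probe.
#' Input is either a list of replicate matrices sharing dimnames
#' (replicate r of sample s is column s of matrix r), or a single matrix of
#' measurement columns plus a [replicate_design()] mapping columns to
#' samples. Probes with zero total variance get `NA` ICC (flagged) rather
#' than failing the whole table; negative between-sample variance estimates
#' are truncated at 0 and flagged.
#'
#' @param reps list of probes x samples matrices with identical dimnames,
#'   or a single probes x measurement-columns matrix.
#' @param design a [replicate_design()]; required when `reps` is a single
#'   matrix.
#' @param conf_level confidence level for the per-probe intervals.
#' @return A data.frame of class `reliability_table` with columns
#'   `probe_id`, `icc`, `icc_lo`, `icc_hi`, `n`, `truncated`.
#' @export
probe_icc_table <- function(reps, design = NULL, conf_level = 0.95) {
  if (is.matrix(reps)) {
    if (is.null(design)) stop_data("a replicate design is required with a single matrix")
    reps <- split_by_design(reps, design)
  }
  if (!is.list(reps) || length(reps) < 2) {
    stop_data("need >= 2 replicate matrices")
  }
  ref <- dimnames(reps[[1]])
  for (r in reps[-1]) {
    if (!identical(rownames(r), ref[[1]])) {
      stop_data(sprintf("replicate probe universes disagree: %d probes mismatched",
                        length(union(setdiff(rownames(r), ref[[1]]),
                                     setdiff(ref[[1]], rownames(r))))))
    }
    if (!identical(colnames(r), ref[[2]])) stop_data("replicate sample columns disagree")
  }
  k <- length(reps)
  n <- ncol(reps[[1]])
  if (n < 2) stop_data("need >= 2 samples")
  has_na <- any(vapply(reps, anyNA, logical(1)))
  if (has_na) return(probe_icc_table_slow(reps, conf_level))

  # balanced design, vectorized over probes
  M <- Reduce(`+`, reps) / k
  ssw <- Reduce(`+`, lapply(reps, function(r) rowSums((r - M)^2)))
  gm <- rowMeans(M)
  ssb <- k * rowSums((M - gm)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  sigma2_b <- (msb - msw) / k
  truncated <- sigma2_b < 0 & (ssb + ssw) > .Machine$double.eps
  sigma2_b <- pmax(0, sigma2_b)
  icc <- sigma2_b / (sigma2_b + msw)
  degenerate <- (ssb + ssw) < .Machine$double.eps
  icc[degenerate] <- NA_real_

  alpha <- 1 - conf_level
  f <- msb / msw
  fl <- f / qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f * qf(1 - alpha / 2, n * (k - 1), n - 1)
  lo <- pmin(1, pmax(0, (fl - 1) / (fl + k - 1)))
  hi <- pmin(1, pmax(0, (fu - 1) / (fu + k - 1)))
  lo[msw <= 0] <- 1
  hi[msw <= 0] <- 1
  lo[degenerate] <- NA_real_
  hi[degenerate] <- NA_real_

  structure(data.frame(probe_id = ref[[1]], icc = icc, icc_lo = lo, icc_hi = hi,
                       n = n, truncated = truncated,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("reliability_table", "data.frame"))
}

split_by_design <- function(m, design) {
  missing_cols <- setdiff(design$replicate_column, colnames(m))
  if (length(missing_cols)) {
    stop_data(sprintf("design references %d columns absent from the matrix (e.g. %s)",
                      length(missing_cols), missing_cols[1]))
  }
  cols_by_sample <- split(design$replicate_column, design$sample_id)
  ks <- lengths(cols_by_sample)
  if (any(ks < 2)) stop_data("every sample in the design needs >= 2 replicate columns")
  k <- max(ks)
  samples <- names(cols_by_sample)
  lapply(seq_len(k), function(r) {
    out <- matrix(NA_real_, nrow(m), length(samples),
                  dimnames = list(rownames(m), samples))
    for (s in samples) {
      cols <- cols_by_sample[[s]]
      if (r <= length(cols)) out[, s] <- m[, cols[r]]
    }
    out
  })
}

probe_icc_table_slow <- function(reps, conf_level) {
  probes <- rownames(reps[[1]])
  rows <- lapply(seq_along(probes), function(i) {
    v <- do.call(cbind, lapply(reps, function(r) r[i, ]))
    est <- tryCatch(estimate_icc(v, conf_level), methylpace_error = function(e) NULL)
    if (is.null(est)) {
      data.frame(probe_id = probes[i], icc = NA_real_, icc_lo = NA_real_,
                 icc_hi = NA_real_, n = sum(rowSums(!is.na(v)) >= 1),
                 truncated = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = probes[i], icc = est$icc, icc_lo = est$lower,
                 icc_hi = est$upper, n = est$n_samples,
                 truncated = est$truncated, stringsAsFactors = FALSE)
    }
  })
  structure(do.call(rbind, rows),
            class = c("reliability_table", "data.frame"))
}

#' Filter probes by a strict ICC threshold
#'
#' Retains probes whose ICC is strictly greater than `threshold` (strict
#' inequality by design), preserving the table's probe order. Probes with
#' `NA` ICC are never retained.
#'
#' @param table a [probe_icc_table()] result (or any data.frame with
#'   `probe_id` and `icc` columns).
#' @param threshold ICC threshold in \[0, 1).
#' @return Character vector of retained probe IDs, with attributes
#'   `n_total` and `n_retained`.
#' @export
filter_probes <- function(table, threshold = 0.4) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1) {
    stop_config("threshold must lie in [0, 1)")
  }
  if (!all(c("probe_id", "icc") %in% names(table))) {
    stop_data("table must have probe_id and icc columns")
  }
  keep <- !is.na(table$icc) & table$icc > threshold
  out <- table$probe_id[keep]
  attr(out, "n_total") <- nrow(table)
  attr(out, "n_retained") <- sum(keep)
  out
}
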