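#' Longitudinal biomarker panel
#'
#' Container for tidy longitudinal biomarker observations plus per-biomarker
#' metadata. `data` holds one row per (subject, visit age, biomarker)
#' measurement; `meta` records, for every biomarker, its orientation (+1 if
#' an increase indicates physiological deterioration, -1 otherwise) and a
#' display name.
#'
#' @param data data.frame with columns `subject_id`, `visit_age`,
#'   `biomarker_id`, `value`.
#' @param meta data.frame with columns `biomarker_id`, `orientation`
#'   (+1 or -1) and `name`.
#' @return An object of class `biomarker_panel` (a list with elements
#'   `data` and `meta`).
#' @export
biomarker_panel <- function(data, meta) {
  data <- as.data.frame(data)
  meta <- as.data.frame(meta)
  need <- c("subject_id", "visit_age", "biomarker_id", "value")
  if (!all(need %in% names(data))) {
    stop_data(sprintf("panel data must have columns %s; missing: %s",
                      paste(need, collapse = ", "),
                      paste(setdiff(need, names(data)), collapse = ", ")))
  }
  if (!all(c("biomarker_id", "orientation") %in% names(meta))) {
    stop_data("biomarker metadata must have columns biomarker_id and orientation")
  }
  if (!"name" %in% names(meta)) meta$name <- meta$biomarker_id
  if (!all(meta$orientation %in% c(-1, 1))) {
    stop_data("biomarker orientation must be +1 or -1 for every biomarker")
  }
  key <- paste(data$subject_id, data$visit_age, data$biomarker_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_data(sprintf("panel contains %d duplicate (subject, visit_age, biomarker) triples",
                      sum(duplicated(key))))
  }
  if (length(unique(data$visit_age)) < 2L) {
    stop_data("panel must contain at least 2 distinct visit ages")
  }
  miss <- setdiff(unique(data$biomarker_id), meta$biomarker_id)
  if (length(miss)) {
    stop_data(sprintf("biomarkers missing from metadata: %s",
                      paste(head(miss, 5), collapse = ", ")))
  }
  structure(list(data = data, meta = meta), class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d observations | %d subjects | %d biomarkers | visit ages: %s\n",
              nrow(x$data), length(unique(x$data$subject_id)),
              length(unique(x$data$biomarker_id)),
              paste(sort(unique(x$data$visit_age)), collapse = ", ")))
  invisible(x)
}
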