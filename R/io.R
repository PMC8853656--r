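# CSV readers and writers for every interchange format (RFC-4180, UTF-8;
# beta matrices may be gzipped). Readers validate schemas and report the
# locations of offending values; writers emit a deterministic column order.

#' Read a beta matrix from CSV/TSV
#'
#' First column must be headed `probe_id`; remaining columns are samples
#' (GEO series-matrix-like orientation). Blank fields and NA tokens become
#' missing; values outside \[0,1\] and duplicate probe IDs are rejected
#' with their locations. Gzipped files are handled transparently.
#'
#' @param path file path (`.csv`, `.tsv`, optionally `.gz`).
#' @return probes x samples numeric matrix.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  dt <- fread_any(path, na.strings = c("", "NA", "NaN"))
  if (names(dt)[1] != "probe_id") {
    stop_data(sprintf("first column must be 'probe_id', found '%s'", names(dt)[1]))
  }
  probes <- as.character(dt[[1]])
  if (anyDuplicated(probes)) {
    dup <- probes[duplicated(probes)]
    stop_data(sprintf("duplicate probe IDs (e.g. %s at row %d)",
                      dup[1], which(probes == dup[1])[2]))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- names(dt)[-1][!vapply(dt[, -1], is.numeric, logical(1))][1]
    stop_data(sprintf("non-numeric values in sample column '%s'", bad_col))
  }
  rownames(m) <- probes
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_data(sprintf(
      "%d beta values outside [0,1]; first offender: value %.4g at row %d (probe %s), sample column '%s'",
      nrow(bad), m[bad[1, 1], bad[1, 2]], bad[1, 1], probes[bad[1, 1]],
      colnames(m)[bad[1, 2]]))
  }
  m
}

#' Write a beta matrix to CSV
#'
#' @param m probes x samples matrix.
#' @param path output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  dt <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fwrite_full(dt, path)
  invisible(path)
}

#' Read a long-format biomarker panel plus metadata
#'
#' @param path panel CSV with columns
#'   `subject_id,visit_age,biomarker_id,value`.
#' @param meta_path biomarker metadata CSV with columns
#'   `biomarker_id,orientation,name`.
#' @return A [biomarker_panel()].
#' @export
read_long_panel <- function(path, meta_path) {
  d <- read_schema_csv(path, c("subject_id", "visit_age", "biomarker_id", "value"))
  meta <- read_schema_csv(meta_path, c("biomarker_id", "orientation"))
  biomarker_panel(d, meta)
}

#' Write a long-format biomarker panel plus metadata
#'
#' @param panel a [biomarker_panel()].
#' @param path,meta_path output CSV paths for observations and metadata.
#' @return `path`, invisibly.
#' @export
write_long_panel <- function(panel, path, meta_path) {
  stopifnot(inherits(panel, "biomarker_panel"))
  fwrite_full(panel$data[c("subject_id", "visit_age", "biomarker_id", "value")], path)
  data.table::fwrite(panel$meta[c("biomarker_id", "orientation", "name")], meta_path)
  invisible(path)
}

#' Read a CpG weight table
#'
#' Expects columns `probe_id,weight`; a row whose `probe_id` is
#' `intercept` populates the intercept (0 when absent, flagged in the
#' provenance). This is the format in which published weight tables for
#' this algorithm family circulate.
#'
#' @param path CSV path.
#' @return A [weight_table()].
#' @export
read_weight_table <- function(path) {
  d <- read_schema_csv(path, c("probe_id", "weight"))
  if (!is.numeric(d$weight)) stop_data(sprintf("non-numeric weights in %s", path))
  is_int <- d$probe_id == "intercept"
  intercept <- if (any(is_int)) d$weight[is_int][1] else 0
  prov <- if (any(is_int)) "" else "no intercept row; intercept set to 0"
  weight_table(intercept, setNames(d$weight[!is_int], d$probe_id[!is_int]),
               provenance = prov)
}

#' Write a CpG weight table
#'
#' @param weights a [weight_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  stopifnot(inherits(weights, "weight_table"))
  d <- data.frame(probe_id = c("intercept", names(weights$weights)),
                  weight = c(weights$intercept, unname(weights$weights)),
                  stringsAsFactors = FALSE)
  fwrite_full(d, path)
  invisible(path)
}

#' Read a probe reliability table
#'
#' @param path CSV with columns `probe_id,icc` (optionally
#'   `icc_lo,icc_hi,n`).
#' @return A `reliability_table` data.frame.
#' @export
read_reliability <- function(path) {
  d <- read_schema_csv(path, c("probe_id", "icc"))
  structure(d, class = c("reliability_table", "data.frame"))
}

#' Write a probe reliability table
#'
#' @param table a [probe_icc_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reliability <- function(table, path) {
  cols <- intersect(c("probe_id", "icc", "icc_lo", "icc_hi", "n"), names(table))
  fwrite_full(as.data.frame(table)[cols], path)
  invisible(path)
}

#' Write Pace of Aging scores
#'
#' @param scores a [compute_pace()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pace_scores <- function(scores, path) {
  fwrite_full(as.data.frame(scores)[
    c("subject_id", "pace", "raw_composite", "n_biomarkers_observed")], path)
  invisible(path)
}

#' Read Pace of Aging scores
#'
#' @param path CSV with columns `subject_id,pace`.
#' @return A `pace_scores`-shaped data.frame.
#' @export
read_pace_scores <- function(path) {
  d <- read_schema_csv(path, c("subject_id", "pace"))
  structure(d, class = c("pace_scores", "data.frame"))
}

#' Write methylation scores
#'
#' @param result a [score()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_result <- function(result, path) {
  fwrite_full(as.data.frame(result)[
    c("sample_id", "score", "frac_algo_probes", "frac_panel_probes",
      "n_imputed", "flag")], path)
  invisible(path)
}

#' Read a replicate design
#'
#' @param path CSV with columns `sample_id,replicate_column`.
#' @return A [replicate_design()].
#' @export
read_replicate_design <- function(path) {
  d <- read_schema_csv(path, c("sample_id", "replicate_column"))
  replicate_design(d$sample_id, d$replicate_column)
}

# Write a data.frame with round-trip numeric precision: doubles are
# serialized as shortest-exact %.17g strings (fwrite's default is 15
# significant digits, which is lossy).
fwrite_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      out <- sprintf("%.17g", df[[j]])
      shorter <- sprintf("%.15g", df[[j]])
      exact <- as.numeric(shorter) == df[[j]] & !is.na(df[[j]])
      out[exact] <- shorter[exact]
      out[is.na(df[[j]])] <- NA
      df[[j]] <- out
    }
  }
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

# fread with transparent gzip handling (decompressed through a gzfile
# connection so no optional helper packages are needed)
fread_any <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  d <- as.data.frame(fread_any(path, na.strings = c("", "NA")))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_data(sprintf("%s: missing required column(s): %s",
                      path, paste(missing, collapse = ", ")))
  }
  d
}
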