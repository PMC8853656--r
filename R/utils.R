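# Internal helpers: classed conditions, seeded evaluation, probe ids.

mp_stop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "methylpace_error", "error")))
}

# configuration / usage errors (CLI exit 2)
stop_config <- function(msg, ...) mp_stop(msg, "mp_config_error", ...)
# data / validation errors (CLI exit 3)
stop_data <- function(msg, ...) mp_stop(msg, "mp_data_error", ...)
# numerical / fitting failures (CLI exit 4)
stop_fit <- function(msg, ...) mp_stop(msg, "mp_fit_error", ...)

# Evaluate fn() under a local seed; NULL seed uses (and advances) the
# session RNG state. All package randomness flows through this.
run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

# Illumina-style probe identifiers: "cg" + zero-padded 8-digit integer,
# unique, sorted. Must be called inside a seeded context.
cg_probe_ids <- function(n) {
  if (n > 99999999L) stop_config("cannot generate more than 1e8 distinct probe ids")
  sprintf("cg%08d", sort(sample.int(99999999L, n)))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
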