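# Internal argument-checking helpers. All validation errors name the offending
# field so that callers (and the table validators in io.R) can surface precise
# messages.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_field(field, "must be numeric and non-missing")
  }
  if (finite && any(!is.finite(x))) stop_field(field, "must be finite")
  if (any(x <= 0)) stop_field(field, "must be > 0")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_field(field, "must be numeric and non-missing")
  }
  if (any(x < 0)) stop_field(field, "must be >= 0")
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_seed <- function(seed, field = "seed") {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop_field(field, "must be a single integer")
  }
  invisible(as.integer(seed))
}

# Derive a generator-specific RNG substream from one top-level seed so that
# adding a generator does not reshuffle the draws of the others. Offsets are
# fixed per generator; the sum is kept inside the 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
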