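# Internal helpers shared across modules.

#' Evaluate an expression with a local, seeded RNG
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed determines every draw and the
#' caller's global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a stream of child seeds from one parent seed
#'
#' Child seeds stay below 2^31 so they remain valid R integers.
#' @noRd
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical string key for a directed edge; used to align edges across
# methods and to detect duplicates.
edge_key <- function(regulator, target) {
  paste(regulator, target, sep = "\r")
}

# Structured progress messages; kept on stderr so stdout stays parseable.
log_msg <- function(...) {
  message("[grnscore] ", ...)
}

# Numeric formatting used by all writers: round-trips doubles exactly
# through text while keeping integers clean.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
}

stop_located <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}
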