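# Internal helpers shared across modules.

stop_reach <- function(message, class, ...) {
  abort(message, class = c(class, "reachstart_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE, class = "reachstart_error_invalid_model") {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x) ||
      any(!is.finite(x))) {
    stop_reach(sprintf("`%s` must be finite numeric.", name), class)
  }
  if (any(x < lower) || any(x > upper)) {
    stop_reach(
      sprintf("`%s` must lie in [%s, %s].", name, format(lower), format(upper)),
      class
    )
  }
  invisible(x)
}

# All stochastic code runs under an explicit integer seed without disturbing
# the caller's RNG state; seed = NULL keeps the ambient stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      stop_reach("`seed` must be a single integer or NULL.",
                 "reachstart_error_invalid_model")
    }
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive independent child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed_or_not(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
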