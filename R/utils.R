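# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats sd
zscore_pop <- function(x) {
  # z-score with the population (divide-by-n) standard deviation;
  # degenerate (zero-spread) vectors map to all zeros rather than NaN
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - m) / s
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
    stop_param(field, "must be a single positive integer")
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_param(field, sprintf("must be a number in [%g, %g]", lo, hi))
  as.numeric(x)
}

# seeded evaluation that never disturbs the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
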