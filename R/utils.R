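# Internal helpers shared across modules.

# Round half away from zero (printed tables use this convention, unlike
# base round()'s round-half-even).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a deterministic sub-seed for a named random stream from one global
# integer seed. Each generator design owns a stream so adding a design never
# perturbs draws in another. All arithmetic stays exact in doubles (< 2^53)
# and the result fits a 32-bit integer seed.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 1000003 + (seed %% 2147483647)) %% 2147483647)
}

# Evaluate `expr` under a seed without disturbing the caller's RNG state.
with_stream_seed <- function(seed, stream, expr) {
  withr::with_seed(stream_seed(seed, stream), expr)
}

# Bounded one-parameter SSR minimisation on (lower, upper]. Rate constants
# span orders of magnitude, so a blind golden-section over the whole
# interval can land on the flat large-rate plateau; a coarse log-spaced
# scan brackets the global minimum first, then scalar optimisation
# refines within the bracket.
minimize_rate <- function(ssr, lower = 1e-8, upper = 10) {
  grid <- 10^seq(log10(lower), log10(upper), length.out = 240)
  vals <- vapply(grid, ssr, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  optimize(ssr, lower = lo, upper = hi, tol = 1e-12)$minimum
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "biosorb_invalid_input")
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    abort(sprintf("`%s` must be %s %s.", name,
                  if (strict_min) ">" else ">=", format(min)),
          class = "biosorb_invalid_input")
  }
  invisible(x)
}
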