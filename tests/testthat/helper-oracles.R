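# Independent oracles used across tests. These deliberately avoid the
# code paths they check.

# Simple-regression normal equations, written out by hand (no lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(
    slope = slope,
    intercept = intercept,
    slope_se = sqrt(s2 / sxx),
    intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  )
}

# k-th positive root of J0 by plain bisection on the bracketing interval
# ((k - 3/4) * pi, (k + 1/4) * pi); independent of uniroot.
bessel_root_bisect <- function(k, tol = 1e-12) {
  lo <- (k - 3 / 4) * pi
  hi <- (k + 1 / 4) * pi
  flo <- besselJ(lo, 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fmid <- besselJ(mid, 0)
    if (sign(fmid) == sign(flo)) {
      lo <- mid
      flo <- fmid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Brute-force grid argmin of a scalar SSR, used as the optimizer oracle.
grid_argmin <- function(f, lower, upper, n = 20001) {
  grid <- seq(lower, upper, length.out = n)
  grid[which.min(vapply(grid, f, numeric(1)))]
}
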