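# Independent brute-force oracles used by the contract tests. These stay
# deliberately naive (dense solves, O(N^2) sums) so they share no code with
# the implementation paths they check.

# dense linear-solve trend estimator: t = (I + lambda^2 D2'D2)^{-1} x
dense_detrend_oracle <- function(x, lambda) {
  n <- length(x)
  D2 <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D2[i, i:(i + 2L)] <- c(1, -2, 1)
  trend <- solve(diag(n) + lambda^2 * (t(D2) %*% D2), x)
  x - as.numeric(trend)
}

# one biased, lag-0-normalized autocorrelation layer by direct summation
lag_sum_autocorr_oracle <- function(x) {
  n <- length(x)
  r <- vapply(0:(n - 1L), function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / n, numeric(1))
  r / r[1]
}

# crossover of the two densities by plain bisection
bisect_crossover_oracle <- function(params, lo, hi, iters = 200L) {
  g <- function(v) live_density(v, params) - false_density(v, params)
  stopifnot(g(lo) > 0, g(hi) < 0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a bin-centered tone at frequency index k (k cycles over n samples)
bin_tone <- function(n, k, fs, amp = 1, phase = 0) {
  amp * sin(2 * pi * k * (0:(n - 1)) / n + phase)
}
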