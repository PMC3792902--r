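#' Smoothness-priors detrending
#'
#' Removes the slowly varying trend from an observed brightness series using
#' the regularized least-squares trend estimator: the trend is
#' \eqn{t = (I + \lambda^2 D_2^\top D_2)^{-1} x}, where \eqn{D_2} is the
#' second-order difference operator of size \eqn{(N-2) \times N}, and the
#' detrended series is \eqn{x - t}. Larger \eqn{\lambda} produces a stiffer
#' trend, i.e. removes only slower components.
#'
#' The solve exploits the banded structure of \eqn{D_2^\top D_2} through a
#' sparse Cholesky factorization.
#'
#' @param x An [observed_series()] or numeric vector, length at least 3.
#' @param lambda Regularization parameter (dimensionless, positive).
#'   Defaults used downstream: 20 for the cardiac series, 300 for the
#'   respiratory series.
#' @return The detrended series, same class and length as `x`.
#' @export
detrend_smoothness_priors <- function(x, lambda = 20) {
  v <- as.numeric(x)
  n <- length(v)
  if (n < 3L) stop("detrend_smoothness_priors: need at least 3 samples")
  if (!all(is.finite(v))) stop("detrend_smoothness_priors: nonfinite input")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("detrend_smoothness_priors: lambda must be a single positive number")
  }
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L),
                                            rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, v))
  out <- v - trend
  if (inherits(x, "observed_series")) rewrap_series(out, x) else out
}

#' Normalize a series to zero mean and unit variance
#'
#' Uses the population (1/N) standard deviation. The scale convention is
#' irrelevant downstream (ICA and spectral ratios are scale-invariant) but
#' is fixed here so results are reproducible to the last digit.
#'
#' @param x An [observed_series()] or numeric vector with non-zero variance.
#' @return Normalized series of the same class; attributes `mean_removed`
#'   and `sd_removed` record the removed statistics.
#' @export
normalize_series <- function(x) {
  v <- as.numeric(x)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) {
    stop("normalize_series: constant input (dead or saturated ROI)")
  }
  out <- (v - mu) / sigma
  out <- if (inherits(x, "observed_series")) rewrap_series(out, x) else out
  attr(out, "mean_removed") <- mu
  attr(out, "sd_removed") <- sigma
  out
}

#' Zero-phase highpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth highpass. Used for
#' small-animal cardiac measurement where whole-body respiratory motion
#' swamps the pulse: e.g. a 5.8 Hz cutoff for mice isolates the cardiac band.
#'
#' @param x An [observed_series()] or numeric vector.
#' @param cutoff Cutoff frequency in Hz, strictly between 0 and the Nyquist
#'   frequency.
#' @param frame_rate Sampling rate in Hz; taken from `x` when it carries one.
#' @return Filtered series, same class and length.
#' @export
highpass_series <- function(x, cutoff, frame_rate = NULL) {
  fs <- series_rate(x, frame_rate)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("highpass_series: cutoff must lie in (0, frame_rate/2)")
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  out <- signal::filtfilt(bf, as.numeric(x))
  if (inherits(x, "observed_series")) rewrap_series(out, x) else out
}
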