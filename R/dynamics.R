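#' Delay-coordinate embedding matrix
#'
#' Reconstructs the state space of the underlying dynamical system from a
#' single observed series by stacking lagged copies: row \eqn{i} (0-based)
#' of the \eqn{m \times n} embedding matrix is the input shifted by
#' \eqn{i \cdot d} samples, with \eqn{n = N - (m-1) d} columns. With the
#' defaults \eqn{m = 3}, \eqn{d = 1} the three rows are the series, and the
#' series delayed by one and two samples.
#'
#' @param x Numeric vector or [observed_series()] (normally the normalized,
#'   detrended series).
#' @param m Embedding dimension (at least 2, or 1 for a passthrough).
#' @param d Delay in samples (positive integer).
#' @return An `m x n` matrix of class `embedding_matrix` with attributes
#'   `m`, `d`, `tau` (delay in seconds, when the input carries a frame rate)
#'   and `frame_rate`.
#' @export
build_embedding <- function(x, m = 3, d = 1) {
  v <- as.numeric(x)
  m <- as.integer(m); d <- as.integer(d)
  if (m < 1L || d < 1L) stop("build_embedding: m and d must be positive")
  n <- length(v) - (m - 1L) * d
  if (n < m) stop("build_embedding: series too short for m=", m, ", d=", d)
  X <- vapply(seq_len(m), function(i) v[seq.int((i - 1L) * d + 1L,
                                                length.out = n)],
              numeric(n))
  X <- t(X)
  fr <- attr(x, "frame_rate")
  structure(X, m = m, d = d, frame_rate = fr,
            tau = if (is.null(fr)) NULL else d / fr,
            class = c("embedding_matrix", "matrix", "array"))
}

#' FastICA decomposition of an embedding matrix
#'
#' Deconstructs the embedding matrix `X` (rows = mixed observations) into
#' statistically independent source signals by the fixed-point FastICA
#' algorithm with the kurtosis (`u^3`) contrast and symmetric decorrelation.
#' The model is \eqn{X = A Y}; the estimated de-mixing matrix \eqn{W}
#' satisfies \eqn{W X_c = Y} with `X_c` the row-centered input, and rows of
#' `Y` have unit (population) variance.
#'
#' @param X An `embedding_matrix` or plain numeric matrix, rows = channels.
#' @param seed Integer seed for the random orthogonal initialization;
#'   results are deterministic given `seed`.
#' @param tol Convergence tolerance on the rotation update (default 1e-6).
#' @param max_iter Maximum fixed-point iterations (default 500).
#' @param on_fail What to do when the update has not settled after
#'   `max_iter` iterations: `"warn"` (default) returns the current estimate
#'   with a warning, `"error"` aborts. Non-settling is expected when two or
#'   more components are nearly Gaussian (e.g. pure noise channels): their
#'   mixing directions form a continuum of equally valid fixed points, the
#'   update drifts within that subspace forever, and any member of the
#'   family is a correct demixing (the reconstruction identity still holds
#'   exactly).
#' @return A list of class `source_set`: `Y` (m x n sources), `A` (mixing),
#'   `W` (de-mixing), `X_centered`, `row_means`, `iterations`, `frame_rate`.
#' @export
fastica_decompose <- function(X, seed = 1L, tol = 1e-6, max_iter = 500L,
                              on_fail = c("warn", "error")) {
  on_fail <- match.arg(on_fail)
  stopifnot(is.matrix(X) || inherits(X, "embedding_matrix"))
  Xm <- unclass(X)
  attr(Xm, "m") <- attr(Xm, "d") <- attr(Xm, "tau") <- NULL
  m <- nrow(Xm); n <- ncol(Xm)
  if (m < 1L || n <= m) stop("fastica_decompose: degenerate input matrix")
  row_means <- rowMeans(Xm)
  Xc <- Xm - row_means
  # whiten
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    stop("fastica_decompose: embedding matrix is rank deficient after ",
         "centering; cannot whiten")
  }
  K <- diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
  Z <- K %*% Xc

  sym_decorrelate <- function(W) {
    es <- eigen(tcrossprod(W), symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(es$values), m) %*% t(es$vectors) %*% W
  }

  W <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(m * m), m, m))
  W <- sym_decorrelate(W)
  W_prev2 <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    U <- W %*% Z
    G <- U^3
    W_new <- G %*% t(Z) / n - diag(rowMeans(3 * U^2), m) %*% W
    W_new <- sym_decorrelate(W_new)
    # one-step criterion, plus a two-step criterion: on nearly sinusoidal
    # input the rotation within the degenerate (sin, cos) subspace is
    # indeterminate and the update settles into a period-2 cycle whose two
    # states are equally valid demixings — accept either fixed point
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    if (!is.null(W_prev2)) {
      delta <- min(delta, max(abs(abs(diag(W_new %*% t(W_prev2))) - 1)))
    }
    W_prev2 <- W
    W <- W_new
    if (delta < tol) break
    if (iter >= max_iter) {
      msg <- paste0("fastica_decompose: update not settled after ", iter,
                    " iterations (last update ", signif(delta, 3), ")")
      if (on_fail == "error") stop(msg)
      warning(msg, "; returning the current estimate")
      break
    }
  }
  W_full <- W %*% K
  structure(list(Y = W_full %*% Xc,
                 A = solve(W_full),
                 W = W_full,
                 X_centered = Xc,
                 row_means = row_means,
                 iterations = iter,
                 frame_rate = attr(X, "frame_rate")),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set: %d components x %d samples (FastICA, %d iter)>\n",
              nrow(x$Y), ncol(x$Y), x$iterations))
  invisible(x)
}

#' Peak power-density ratio
#'
#' The ratio of the highest single-bin power to the total power in the band
#' (0, min(8, Nyquist)] Hz of the one-sided raw periodogram (rectangular
#' window, no zero padding; DC excluded). Near 1 for a dominant periodic
#' rhythm, small for wideband noise — the basic spectral peakedness measure
#' used both for component selection and liveness screening.
#'
#' @param y Numeric vector or [observed_series()], length at least 8.
#' @param frame_rate Sampling rate in Hz (taken from `y` when present).
#' @return A single number in (0, 1].
#' @export
peak_power_ratio <- function(y, frame_rate = NULL) {
  fs <- series_rate(y, frame_rate)
  v <- as.numeric(y)
  N <- length(v)
  if (N < 8L) stop("peak_power_ratio: need at least 8 samples")
  if (all(v == 0)) stop("peak_power_ratio: all-zero input")
  P <- abs(stats::fft(v))^2 / N
  k <- seq_len(floor(N / 2))          # positive-frequency bins, DC excluded
  f <- k * fs / N
  keep <- f <= min(8, fs / 2) + 1e-12
  P <- P[k + 1L][keep]
  if (!length(P) || sum(P) == 0) stop("peak_power_ratio: empty band")
  max(P) / sum(P)
}

series_skewness <- function(v) {
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) return(0)
  mean((v - mu)^3) / s^3
}

#' Select the physiological component from a source set
#'
#' Picks the independent component whose power spectrum has the highest
#' peak-to-total power ratio (ties broken by lowest index) and orients it
#' canonically: the sign is flipped when the component's skewness is
#' negative, so the asymmetric systolic upstroke points upward.
#'
#' @param src A `source_set` from [fastica_decompose()].
#' @param frame_rate Sampling rate in Hz (taken from `src` when present).
#' @return A list with `index`, `signal` (oriented 1-D series) and
#'   `peak_ratio`.
#' @export
select_component <- function(src, frame_rate = NULL) {
  stopifnot(inherits(src, "source_set"))
  fs <- if (!is.null(frame_rate)) frame_rate else src$frame_rate
  if (is.null(fs)) stop("select_component: frame_rate required")
  ratios <- apply(src$Y, 1L, peak_power_ratio, frame_rate = fs)
  idx <- unname(which.max(ratios))    # which.max takes the first maximum
  sig <- src$Y[idx, ]
  if (series_skewness(sig) < 0) sig <- -sig
  list(index = idx, signal = sig, peak_ratio = ratios[idx])
}
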