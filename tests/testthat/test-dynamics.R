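test_that("embedding matrix follows the lag definition", {
  X <- build_embedding(c(1, 2, 3, 4, 5), m = 3, d = 1)
  expect_equal(dim(X), c(3L, 3L))
  expect_equal(unclass(X)[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(unclass(X)[2, ], c(2, 3, 4), ignore_attr = TRUE)
  expect_equal(unclass(X)[3, ], c(3, 4, 5), ignore_attr = TRUE)

  # m = 1 is the series itself; n = N - (m-1) d in general
  expect_equal(as.numeric(build_embedding(1:6, m = 1, d = 1)), as.numeric(1:6))
  expect_equal(ncol(build_embedding(1:6, m = 2, d = 2)), 4L)
  expect_error(build_embedding(1:4, m = 3, d = 2), "too short")
})

test_that("embedding satisfies the row-shift identity exhaustively", {
  set.seed(5)
  for (m in 2:4) for (d in 1:3) {
    N <- m + (m - 1) * d + 7
    x <- rnorm(N)
    X <- unclass(build_embedding(x, m, d))
    n <- ncol(X)
    for (i in seq_len(m - 1)) {
      valid <- seq_len(n - d)
      expect_equal(X[i + 1, valid], X[i, valid + d])
    }
  }
})

test_that("FastICA recovers a known two-source mixture up to sign/permutation", {
  set.seed(8)
  n <- 2000
  t <- (0:(n - 1)) / 100
  s1 <- sign(sin(2 * pi * 1.2 * t)) * (abs(sin(2 * pi * 1.2 * t)))^0.3
  s2 <- runif(n, -1, 1)
  S <- rbind(s1 / sd(s1), s2 / sd(s2))
  A <- matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)
  X <- A %*% S
  src <- fastica_decompose(X, seed = 2)
  cors <- abs(cor(t(src$Y), t(S)))
  # each true source matched by exactly one estimated component
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
  expect_equal(sort(apply(cors, 2, which.max)), c(1, 2))
})

test_that("FastICA reconstruction and determinism contracts hold", {
  set.seed(9)
  x <- sin(2 * pi * 1.3 * (0:299) / 15) + 0.3 * rnorm(300)
  X <- build_embedding(x, 3, 1)
  src <- fastica_decompose(X, seed = 4)
  resid <- norm(src$A %*% src$Y - src$X_centered, "F") /
    norm(src$X_centered, "F")
  expect_lt(resid, 1e-6)
  # unit-variance sources, W X = Y
  expect_equal(apply(src$Y, 1, function(r) mean(r^2)), rep(1, 3),
               tolerance = 1e-8)
  expect_lt(max(abs(src$W %*% src$X_centered - src$Y)), 1e-10)

  src2 <- fastica_decompose(X, seed = 4)
  expect_identical(src$Y, src2$Y)

  # rank-deficient input cannot be whitened
  Xdef <- rbind(x[1:200], x[1:200], rnorm(200))
  expect_error(fastica_decompose(Xdef, seed = 1), "rank deficient")
})

test_that("non-settled iteration errors on request and warns by default", {
  set.seed(10)
  X <- build_embedding(rnorm(200), 3, 1)
  expect_error(fastica_decompose(X, seed = 1, max_iter = 1L,
                                 on_fail = "error"),
               "1 iterations")
  expect_warning(fastica_decompose(X, seed = 1, max_iter = 1L),
                 "not settled")
})

test_that("peak power ratio separates tones from noise", {
  fs <- 15; n <- 300
  tone <- bin_tone(n, 24, fs)                  # 1.2 Hz, bin-centered
  expect_gt(peak_power_ratio(tone, fs), 0.9)

  two <- bin_tone(n, 24, fs) + bin_tone(n, 40, fs)
  expect_equal(peak_power_ratio(two, fs), 0.5, tolerance = 1e-9)

  set.seed(12)
  ratios <- replicate(20, peak_power_ratio(rnorm(512), fs))
  expect_true(mean(ratios < 0.1) >= 0.9)

  expect_error(peak_power_ratio(rep(0, 64), fs), "all-zero")
})

test_that("component selection picks the most peaked row and orients it", {
  set.seed(13)
  n <- 300
  Y <- rbind(rnorm(n), bin_tone(n, 24, 15), rnorm(n))
  Y <- Y / sqrt(rowMeans(Y^2))
  src <- structure(list(Y = Y, frame_rate = 15), class = "source_set")
  sel <- select_component(src)
  expect_identical(sel$index, 2L)

  # ties break to the lowest index
  Yt <- rbind(bin_tone(n, 24, 15), bin_tone(n, 24, 15), bin_tone(n, 24, 15))
  srct <- structure(list(Y = Yt, frame_rate = 15), class = "source_set")
  expect_identical(select_component(srct)$index, 1L)

  # negative-skew component comes back flipped to positive skew
  skewed <- -exp(bin_tone(n, 24, 15))         # sharp downward pulses
  stopifnot(mean((skewed - mean(skewed))^3) < 0)
  src2 <- structure(list(Y = rbind(pulse = skewed, noise = rnorm(n) * 0.1),
                         frame_rate = 15), class = "source_set")
  sel2 <- select_component(src2)
  expect_identical(sel2$index, 1L)
  expect_equal(sel2$signal, -skewed, ignore_attr = TRUE)
})

test_that("rate estimates are indifferent to component scale and sign", {
  set.seed(14)
  y <- bin_tone(450, 36, 15) + 0.2 * rnorm(450)
  rate_of <- function(v) {
    sm <- moving_average(v, 5)
    ac <- autocorr_three_layer(sm)
    power_spectrum(ac, 15, band = c(0.7, 4))$peak_freq * 60
  }
  r0 <- rate_of(y)
  expect_equal(rate_of(-3.7 * y), r0)
  expect_equal(rate_of(0.01 * y), r0)
})
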