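test_that("density evaluations reproduce the published worked examples", {
  expect_identical(round(live_density(0.49), 3), 0.016)
  expect_identical(round(false_density(0.49), 2), 2.78)
  # the exact Gamma pdf at 0.72 is 4.267e-4; the printed 4.24e-4 carries a
  # rounding artifact, so compare at 1% relative
  expect_equal(live_density(0.72), 4.24e-4, tolerance = 0.01)
  expect_identical(round(false_density(0.72), 2), 0.77)

  expect_identical(classify_liveness(0.49)$label, "inanimate")
  expect_identical(classify_liveness(0.72)$label, "inanimate")
})

test_that("both densities integrate to one and the Gaussian is symmetric", {
  pp <- pd_params()
  ig <- integrate(live_density, 0, Inf, params = pp, rel.tol = 1e-9)
  expect_equal(ig$value, 1, tolerance = 1e-6)
  inorm <- integrate(false_density, -Inf, Inf, params = pp, rel.tol = 1e-9)
  expect_equal(inorm$value, 1, tolerance = 1e-6)
  for (dx in c(0.05, 0.2, 0.4)) {
    expect_equal(false_density(pp$gauss_mean + dx),
                 false_density(pp$gauss_mean - dx))
  }
  expect_equal(live_density(0), 0)     # shape > 1 vanishes at the origin
})

test_that("classification is a threshold rule at the density crossover", {
  pp <- pd_params()
  nu_star <- bisect_crossover_oracle(pp, lo = 0.05, hi = pp$gauss_mean)
  expect_equal(liveness_crossover(pp), nu_star, tolerance = 1e-9)
  eps <- 1e-6
  expect_identical(classify_liveness(nu_star - eps, pp)$label, "live")
  expect_identical(classify_liveness(nu_star + eps, pp)$label, "inanimate")
  # the live region is the interval between the two crossings: scan a grid
  grid <- seq(0.001, 1.2, by = 0.001)
  live <- classify_liveness(grid, pp)$label == "live"
  runs <- rle(live)
  expect_lte(sum(runs$values), 1L)     # at most one contiguous live run
  expect_lt(max(grid[live]), nu_star + 1e-3)
})

test_that("ratio variation vanishes for smoothing-invariant tones", {
  fs <- 15
  tone <- bin_tone(150, 10, fs)        # 1 Hz, bin-centered
  rv <- ratio_variation(tone, fs, 5)
  expect_lt(rv$nu, 0.05)
  # r_pre == r_post forces nu = 0 by construction
  k1 <- moving_average(tone, 1)        # identity smoothing
  rv0 <- ratio_variation(tone, fs, 1)
  expect_equal(rv0$nu, 0)
})

test_that("accumulated rule needs three values and never flips agreement", {
  expect_error(classify_accumulated(c(0.1, 0.2)), "three")
  expect_error(classify_accumulated(rep(0.1, 4)), "three")
  expect_identical(classify_accumulated(rep(0.49, 3))$label, "inanimate")

  set.seed(19)
  pp <- pd_params()
  for (i in 1:200) {
    nus <- runif(3, 0, 1)
    singles <- classify_liveness(nus, pp)$label
    if (length(unique(singles)) == 1L) {
      expect_identical(classify_accumulated(nus, pp)$label, singles[1])
    }
  }
})

test_that("accumulation beats single windows under the reference densities", {
  # draws from the fitted reference world: live ~ Gamma, inanimate ~
  # truncated Gaussian; accumulated three-window sums must reduce both
  # error rates relative to per-window classification
  set.seed(20)
  pp <- pd_params()
  n <- 3000
  nu_l <- matrix(rgamma(3 * n, shape = pp$gamma_shape,
                        scale = pp$gamma_scale), ncol = 3)
  nu_f <- matrix(abs(rnorm(3 * n, pp$gauss_mean, pp$gauss_sd)), ncol = 3)
  single_fn <- mean(classify_liveness(as.numeric(nu_l), pp)$label == "inanimate")
  single_fp <- mean(classify_liveness(as.numeric(nu_f), pp)$label == "live")
  acc_fn <- mean(vapply(seq_len(n), function(i)
    classify_accumulated(nu_l[i, ], pp)$label == "inanimate", logical(1)))
  acc_fp <- mean(vapply(seq_len(n), function(i)
    classify_accumulated(nu_f[i, ], pp)$label == "live", logical(1)))
  expect_lt(acc_fp, single_fp)
  expect_lt(acc_fn, single_fn)
})

test_that("density fitting recovers generating parameters", {
  set.seed(22)
  nus_t <- rgamma(500, shape = 1.5335, scale = 0.0599)
  nus_f <- rnorm(500, 0.4905, 0.1434)
  fit <- suppressWarnings(fit_pds(nus_t, nus_f))
  expect_lt(abs(fit$params$gamma_shape - 1.5335) / 1.5335, 0.15)
  expect_lt(abs(fit$params$gamma_scale - 0.0599) / 0.0599, 0.15)
  expect_lt(abs(fit$params$gauss_mean - 0.4905), 0.02)
  expect_lt(abs(fit$params$gauss_sd - 0.1434), 0.02)
  expect_true(all(fit$ks$p_value > 0.01))

  td <- tidy(fit)
  expect_identical(td$term[1], "gamma_shape")
  expect_identical(nrow(glance(fit)), 1L)

  expect_error(fit_pds(nus_t[1:10], nus_f), "at least 50")
  expect_error(fit_pds(c(nus_t[-1], -0.1), nus_f), "positive")
})

test_that("KS p-values are roughly uniform under the null", {
  set.seed(23)
  pvals <- replicate(40, {
    fit <- suppressWarnings(
      fit_pds(rgamma(120, 1.5, scale = 0.06), rnorm(120, 0.5, 0.15)))
    fit$ks$p_value
  })
  # no pile-up at zero: the empirical CDF of p at 0.1 stays near 0.1
  expect_lt(mean(pvals < 0.1), 0.3)
  expect_gt(mean(pvals > 0.5), 0.25)
})

test_that("error rates match direct 2x2 table counting", {
  truth <- c(rep("live", 6), rep("inanimate", 4))
  verdict <- c("live", "live", "inanimate", "live", "inanimate", "live",
               "live", "inanimate", "inanimate", "live")
  er <- error_rates(truth, verdict)
  expect_equal(er$fp_rate, 2 / 4)
  expect_equal(er$fn_rate, 2 / 6)

  perfect <- error_rates(truth, truth)
  expect_equal(c(perfect$fp_rate, perfect$fn_rate), c(0, 0))
  flipped <- ifelse(truth == "live", "inanimate", "live")
  er2 <- error_rates(truth, flipped)
  expect_equal(c(er2$fp_rate, er2$fn_rate), c(1, 1))

  expect_error(error_rates(rep("live", 3), rep("live", 2)), "lengths")
  expect_error(error_rates(rep("live", 3), rep("live", 3)), "both classes")
})
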