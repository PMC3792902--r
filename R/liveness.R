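#' Fitted ratio-variation probability-density parameters
#'
#' The liveness classifier compares the ratio-variation statistic against
#' two fitted densities: a Gamma density for live subjects and a Gaussian
#' for inanimate figures. The defaults are the constants fitted on 500 live
#' and 500 inanimate measurements (15 fps, 10 s windows).
#'
#' @param gamma_shape,gamma_scale Gamma shape `a` and scale `b` of the live
#'   density (defaults 1.5335 and 0.0599).
#' @param gauss_mean,gauss_sd Mean and standard deviation of the inanimate
#'   Gaussian density (defaults 0.4905 and 0.1434).
#' @return A list of class `pd_params`.
#' @export
pd_params <- function(gamma_shape = 1.5335, gamma_scale = 0.0599,
                      gauss_mean = 0.4905, gauss_sd = 0.1434) {
  if (gamma_shape <= 0 || gamma_scale <= 0) {
    stop("pd_params: Gamma shape and scale must be positive")
  }
  if (gauss_sd <= 0) stop("pd_params: Gaussian sd must be positive")
  structure(list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 gauss_mean = gauss_mean, gauss_sd = gauss_sd),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("<pd_params: live ~ Gamma(a=%.4g, b=%.4g), ", x$gamma_shape,
              x$gamma_scale),
      sprintf("inanimate ~ N(%.4g, %.4g)>\n", x$gauss_mean, x$gauss_sd),
      sep = "")
  invisible(x)
}

#' Density of the live (Gamma) ratio-variation distribution
#'
#' @param nu Ratio-variation value(s), non-negative.
#' @param params A [pd_params()].
#' @return `f_T(nu)`, the Gamma density at `nu`.
#' @export
live_density <- function(nu, params = pd_params()) {
  if (any(nu < 0)) stop("live_density: nu must be non-negative")
  stats::dgamma(nu, shape = params$gamma_shape, scale = params$gamma_scale)
}

#' Density of the inanimate (Gaussian) ratio-variation distribution
#'
#' @inheritParams live_density
#' @return `f_F(nu)`, the Gaussian density at `nu`.
#' @export
false_density <- function(nu, params = pd_params()) {
  stats::dnorm(nu, mean = params$gauss_mean, sd = params$gauss_sd)
}

#' Ratio-variation statistic of a source signal
#'
#' Measures how much the spectral peak power-density ratio `R` changes when
#' the source signal is moving-average smoothed. A live subject's dominant
#' physiological rhythm keeps `R` nearly unchanged (the peak survives
#' smoothing), so the relative variation
#' \eqn{\nu = |R_{pre} - R_{post}| / R_{post}} is small; wideband noise from
#' an inanimate subject redistributes power under smoothing and yields a
#' large variation.
#'
#' @param y 1-D source signal (numeric or [observed_series()]).
#' @param frame_rate Sampling rate in Hz (taken from `y` when present).
#' @param ma_window Odd moving-average window in samples (5 for cardiac).
#' @return A list with `r_pre`, `r_post` and `nu`.
#' @export
ratio_variation <- function(y, frame_rate = NULL, ma_window = 5L) {
  fs <- series_rate(y, frame_rate)
  r_pre <- peak_power_ratio(y, fs)
  r_post <- peak_power_ratio(moving_average(as.numeric(y), ma_window), fs)
  list(r_pre = r_pre, r_post = r_post, nu = abs(r_pre - r_post) / r_post)
}

#' Classify a measurement as live or inanimate
#'
#' A measurement with ratio-variation `nu` is labelled live exactly when
#' the live density exceeds the inanimate density at `nu`; ties go to
#' inanimate (the conservative choice for a vital-signs alarm).
#'
#' @param nu Ratio-variation value(s), non-negative; vectorized.
#' @param params A [pd_params()].
#' @return A tibble with one row per `nu`: `nu`, `f_live`, `f_false`,
#'   `label` (`"live"` or `"inanimate"`).
#' @export
classify_liveness <- function(nu, params = pd_params()) {
  if (any(!is.finite(nu)) || any(nu < 0)) {
    stop("classify_liveness: nu must be finite and non-negative")
  }
  ft <- live_density(nu, params)
  ff <- false_density(nu, params)
  tibble::tibble(nu = nu, f_live = ft, f_false = ff,
                 label = ifelse(ft > ff, "live", "inanimate"))
}

#' Accumulated three-window liveness decision
#'
#' Sums the two densities over three successive measurements (10 s windows
#' taken 5 s apart) and labels the subject live only when the accumulated
#' live probability exceeds the accumulated inanimate probability. Pooling
#' three windows suppresses the borderline single-window errors caused by
#' the crossover region of the two densities.
#'
#' @param nus Exactly three ratio-variation values.
#' @param params A [pd_params()].
#' @return A one-row tibble: `f_live_sum`, `f_false_sum`, `label`.
#' @export
classify_accumulated <- function(nus, params = pd_params()) {
  if (length(nus) != 3L) {
    stop("classify_accumulated: exactly three successive measurements ",
         "are required")
  }
  if (any(!is.finite(nus)) || any(nus < 0)) {
    stop("classify_accumulated: nu values must be finite and non-negative")
  }
  ft <- sum(live_density(nus, params))
  ff <- sum(false_density(nus, params))
  tibble::tibble(f_live_sum = ft, f_false_sum = ff,
                 label = if (ft > ff) "live" else "inanimate")
}

#' Decision boundary of the two ratio-variation densities
#'
#' The classifier's live region is an interval of `nu`: the Gamma density
#' dominates between a vanishingly small lower crossover (where it rises
#' from zero, around 1e-8 with the default parameters — numerically
#' irrelevant) and the decision boundary returned here, the root of
#' `f_T(nu) = f_F(nu)` between the Gamma mode and the Gaussian mean.
#'
#' @param params A [pd_params()] with `gamma_shape > 1`.
#' @return The boundary value of `nu`; measurements above it are labelled
#'   inanimate.
#' @export
liveness_crossover <- function(params = pd_params()) {
  g <- function(v) live_density(v, params) - false_density(v, params)
  mode <- (params$gamma_shape - 1) * params$gamma_scale
  if (mode <= 0 || g(mode) <= 0) {
    stop("liveness_crossover: densities do not cross between the Gamma ",
         "mode and the Gaussian mean for these parameters")
  }
  stats::uniroot(g, lower = mode, upper = params$gauss_mean,
                 tol = 1e-12)$root
}

#' Fit the ratio-variation densities from labelled samples
#'
#' Fits the live Gamma density by maximum likelihood and the inanimate
#' Gaussian by moments, and reports a Kolmogorov-Smirnov goodness-of-fit
#' test of each sample against its fitted family.
#'
#' @param nus_live Ratio-variation samples from live subjects (all
#'   positive; at least 50).
#' @param nus_false Samples from inanimate subjects (at least 50).
#' @return A list of class `pd_fit`: `params` (a [pd_params()]) and `ks`, a
#'   tibble with one row per family (`statistic`, `p_value`, `n`).
#' @export
fit_pds <- function(nus_live, nus_false) {
  if (length(nus_live) < 50L || length(nus_false) < 50L) {
    stop("fit_pds: need at least 50 samples in each class")
  }
  if (any(nus_live <= 0)) {
    stop("fit_pds: live samples must be strictly positive for a Gamma fit")
  }
  gfit <- MASS::fitdistr(nus_live, "gamma")
  shape <- unname(gfit$estimate["shape"])
  rate <- unname(gfit$estimate["rate"])
  mu <- mean(nus_false)
  sigma <- stats::sd(nus_false)
  ks_g <- suppressWarnings(
    stats::ks.test(nus_live, "pgamma", shape = shape, rate = rate))
  ks_n <- suppressWarnings(
    stats::ks.test(nus_false, "pnorm", mean = mu, sd = sigma))
  structure(list(
    params = pd_params(gamma_shape = shape, gamma_scale = 1 / rate,
                       gauss_mean = mu, gauss_sd = sigma),
    ks = tibble::tibble(
      family = c("gamma_live", "gaussian_inanimate"),
      statistic = c(unname(ks_g$statistic), unname(ks_n$statistic)),
      p_value = c(ks_g$p.value, ks_n$p.value),
      n = c(length(nus_live), length(nus_false)))),
    class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  print(x$params)
  print(x$ks)
  invisible(x)
}

#' @rdname fit_pds
#' @param x A `pd_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma_shape", "gamma_scale", "gauss_mean", "gauss_sd"),
    estimate = c(x$params$gamma_shape, x$params$gamma_scale,
                 x$params$gauss_mean, x$params$gauss_sd))
}

#' @rdname fit_pds
#' @exportS3Method generics::glance
glance.pd_fit <- function(x, ...) {
  tibble::tibble(
    ks_stat_live = x$ks$statistic[1], ks_p_live = x$ks$p_value[1],
    ks_stat_inanimate = x$ks$statistic[2], ks_p_inanimate = x$ks$p_value[2],
    n_live = x$ks$n[1], n_inanimate = x$ks$n[2])
}

#' False-positive and false-negative rates of liveness verdicts
#'
#' The false-positive rate is the fraction of inanimate subjects labelled
#' live; the false-negative rate is the fraction of live subjects labelled
#' inanimate.
#'
#' @param truth Character vector of true classes, `"live"` or
#'   `"inanimate"`.
#' @param verdict Character vector (or tibble with a `label` column) of
#'   classifier verdicts, same length.
#' @return A one-row tibble: `fp_rate`, `fn_rate`, `n_live`,
#'   `n_inanimate`.
#' @export
error_rates <- function(truth, verdict) {
  if (is.data.frame(verdict)) verdict <- verdict$label
  if (length(truth) != length(verdict)) {
    stop("error_rates: truth and verdict lengths differ")
  }
  ok <- c("live", "inanimate")
  if (!all(truth %in% ok) || !all(verdict %in% ok)) {
    stop("error_rates: labels must be 'live' or 'inanimate'")
  }
  n_live <- sum(truth == "live")
  n_inan <- sum(truth == "inanimate")
  if (n_live == 0L || n_inan == 0L) {
    stop("error_rates: both classes must be represented")
  }
  tibble::tibble(
    fp_rate = sum(truth == "inanimate" & verdict == "live") / n_inan,
    fn_rate = sum(truth == "live" & verdict == "inanimate") / n_live,
    n_live = n_live, n_inanimate = n_inan)
}
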