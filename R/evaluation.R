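#' Bland-Altman agreement between two rate series
#'
#' Summarizes the agreement between rates measured by this method and a
#' contact reference (e.g. ECG-derived): mean of the paired differences,
#' their sample (n-1) standard deviation, the 95% limits of agreement
#' (mean difference +/- 1.96 SD), the root-mean-square error (population
#' mean of squared differences), and the Pearson correlation of the two
#' series.
#'
#' @param method Numeric vector of rates from the camera method, or a data
#'   frame holding both series.
#' @param reference Numeric vector of reference rates (same length), or —
#'   when `method` is a data frame — the two column names, unquoted, via
#'   `method_col` / `reference_col`.
#' @param method_col,reference_col Columns to use when `method` is a data
#'   frame (tidy-eval; defaults `method` and `reference`).
#' @return An object of class `bland_altman` with `stats` (one-row tibble:
#'   `n_pairs`, `mean_diff`, `sd_diff`, `upper_limit`, `lower_limit`,
#'   `rmse`, `r`) and `data` (tibble of pairs, means and differences).
#'   When either series has zero variance the correlation is undefined;
#'   `r` is `NA` and a warning is raised.
#' @examples
#' ref <- c(60, 65, 70, 75, 80)
#' bland_altman(ref + c(1, -1, 2, 0, -2), ref)
#' @export
bland_altman <- function(method, reference = NULL,
                         method_col = NULL, reference_col = NULL) {
  if (is.data.frame(method)) {
    df <- method
    mq <- rlang::enquo(method_col)
    rq <- rlang::enquo(reference_col)
    m <- if (rlang::quo_is_null(mq)) df[["method"]]
         else rlang::eval_tidy(mq, df)
    r <- if (rlang::quo_is_null(rq)) df[["reference"]]
         else rlang::eval_tidy(rq, df)
    if (is.null(m) || is.null(r)) {
      stop("bland_altman: data frame input needs 'method' and 'reference' ",
           "columns (or method_col/reference_col)")
    }
  } else {
    m <- as.numeric(method)
    r <- as.numeric(reference)
  }
  if (length(m) != length(r)) stop("bland_altman: length mismatch")
  if (length(m) < 2L) stop("bland_altman: need at least 2 pairs")
  if (any(!is.finite(m)) || any(!is.finite(r))) {
    stop("bland_altman: nonfinite rates")
  }
  d <- m - r
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  rmse <- sqrt(mean(d^2))
  if (stats::sd(m) == 0 || stats::sd(r) == 0) {
    warning("bland_altman: zero variance in a series; ",
            "correlation undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(m, r)
  }
  structure(list(
    stats = tibble::tibble(
      n_pairs = length(m), mean_diff = mean_diff, sd_diff = sd_diff,
      upper_limit = mean_diff + 1.96 * sd_diff,
      lower_limit = mean_diff - 1.96 * sd_diff,
      rmse = rmse, r = rho),
    data = tibble::tibble(method = m, reference = r,
                          mean = (m + r) / 2, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  print(x$stats)
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    term = c("mean_diff", "sd_diff", "upper_limit", "lower_limit",
             "rmse", "r"),
    estimate = c(s$mean_diff, s$sd_diff, s$upper_limit, s$lower_limit,
                 s$rmse, s$r))
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) x$stats

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = s$mean_diff) +
    ggplot2::geom_hline(yintercept = c(s$lower_limit, s$upper_limit),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (method - reference)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Plot per-window vital-sign estimates
#'
#' @param estimates A tibble from [estimate_vitals()] (optionally several,
#'   row-bound with a `kind` column).
#' @return A ggplot of rate against window center time.
#' @export
plot_vitals <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  p <- ggplot2::ggplot(
    dplyr::filter(estimates, !.data$flagged),
    ggplot2::aes(x = .data$t_center_s, y = .data$rate_per_min))
  if ("kind" %in% names(estimates)) {
    p <- p + ggplot2::aes(colour = .data$kind)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Window center (s)", y = "Rate (per minute)") +
    ggplot2::theme_minimal()
}

#' Plot a one-sided power spectrum
#'
#' @param object A `spectrum_result` from [power_spectrum()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_result <- function(object, ...) {
  df <- tibble::tibble(freq = object$freq, power = object$power)
  df <- dplyr::filter(df, .data$freq <= min(8, object$frame_rate / 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_freq, linetype = "dotted") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  subtitle = sprintf("peak %.3g Hz (%.0f per minute)",
                                     object$peak_freq,
                                     object$peak_freq * 60)) +
    ggplot2::theme_minimal()
}
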