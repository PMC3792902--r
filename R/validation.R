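#' Synthetic rate-recovery study
#'
#' Generates an ensemble of synthetic subjects with known heart and
#' respiration rates, runs the full estimation chain on each, and reports
#' the recovery errors. The default conditions are the human study
#' conditions: 30 s recordings at 15 fps, heart rate uniform in 50-110 bpm,
#' respiration uniform in 10-25 breaths/min, cardiac signal-to-noise ratio
#' (amplitude^2 / (2 noise_sd^2)) uniform in 3-10.
#'
#' @param n Number of subjects.
#' @param seed Integer seed controlling every random draw.
#' @param frame_rate,duration Recording geometry (Hz, s).
#' @param hr_range,rr_range Rate ranges (bpm, breaths/min).
#' @param snr_range Signal-to-noise ratio range for both modulations.
#' @return A tibble with one row per subject: true and estimated rates and
#'   absolute errors (`hr_true`, `hr_est`, `hr_err`, `rr_true`, `rr_est`,
#'   `rr_err`).
#' @export
synthetic_recovery_study <- function(n = 100, seed = 1L, frame_rate = 15,
                                     duration = 30,
                                     hr_range = c(50, 110),
                                     rr_range = c(10, 25),
                                     snr_range = c(3, 10)) {
  seed <- as.integer(seed)
  draws <- withr::with_seed(seed, list(
    hr = stats::runif(n, hr_range[1], hr_range[2]),
    rr = stats::runif(n, rr_range[1], rr_range[2]),
    snr = stats::runif(n, snr_range[1], snr_range[2])))
  cfg_b <- rate_config("bvp", window_s = duration, stride_s = duration)
  cfg_r <- rate_config("resp", window_s = duration, stride_s = duration)
  rows <- purrr::map(seq_len(n), function(i) {
    p <- scene_params(frame_rate = frame_rate, duration = duration,
                      hr_freq = draws$hr[i] / 60, rr_freq = draws$rr[i] / 60,
                      noise_sd = 3 / sqrt(2 * draws$snr[i]),
                      seed = seed + 17L * i)
    eb <- estimate_vitals(generate_vital_series(p, "cardiac"), cfg_b,
                          seed = seed + 2L * i)
    er <- estimate_vitals(generate_vital_series(p, "respiratory"), cfg_r,
                          seed = seed + 2L * i + 1L)
    tibble::tibble(subject = i, snr = draws$snr[i],
                   hr_true = draws$hr[i], hr_est = eb$rate_per_min[1],
                   rr_true = draws$rr[i], rr_est = er$rate_per_min[1])
  })
  dplyr::mutate(dplyr::bind_rows(rows),
                hr_err = abs(.data$hr_est - .data$hr_true),
                rr_err = abs(.data$rr_est - .data$rr_true))
}

# per-subject ratio-variation triple: three 10 s windows taken 5 s apart
liveness_subject_nus <- function(live, snr, seed, frame_rate = 15,
                                 window_s = 10, stride_s = 5) {
  p <- scene_params(frame_rate = frame_rate,
                    duration = window_s + 2 * stride_s,
                    hr_freq = withr::with_seed(seed,
                                               stats::runif(1, 50, 110) / 60),
                    noise_sd = 3 / sqrt(2 * snr), seed = seed)
  if (!live) {
    p$cardiac_amp <- 0
    p$resp_amp <- 0
  }
  cfg <- rate_config("bvp", window_s = window_s, stride_s = stride_s)
  est <- estimate_vitals(generate_vital_series(p, "cardiac"), cfg,
                         seed = seed + 1L)
  est$nu[1:3]
}

#' Synthetic liveness study: single-window versus accumulated rule
#'
#' Emulates the false-signal evaluation protocol: ratio-variation densities
#' are first fitted on an independent training ensemble of live and
#' inanimate synthetic subjects, then a test ensemble is classified with
#' the fitted densities by (a) the single-window rule applied to every
#' 10 s window and (b) the accumulated rule applied to each subject's
#' three successive windows (10 s long, taken 5 s apart). Live subjects
#' span a wide signal-to-noise range (default 1-6, reaching down to noisy
#' nighttime conditions) so that single-window errors occur; inanimate
#' subjects are drift + flicker + noise scenes.
#'
#' @param n_test Test subjects per class.
#' @param n_train Training subjects per class used to fit the densities.
#' @param seed Integer seed.
#' @param snr_range Live-subject signal-to-noise range.
#' @param frame_rate Frames per second.
#' @return A list of class `liveness_study`: `fit` (the [fit_pds()]
#'   result), `single` and `accumulated` (one-row [error_rates()] tibbles),
#'   and `nus` (tibble of all test ratio-variation values).
#' @export
synthetic_liveness_study <- function(n_test = 200, n_train = 100,
                                     seed = 1L, snr_range = c(1, 6),
                                     frame_rate = 15) {
  seed <- as.integer(seed)
  gather <- function(n, live, seed0) {
    snr <- withr::with_seed(seed0, stats::runif(n, snr_range[1],
                                                snr_range[2]))
    purrr::map(seq_len(n), function(i)
      liveness_subject_nus(live, snr[i], seed = seed0 + 31L * i,
                           frame_rate = frame_rate))
  }
  tr_live <- unlist(gather(n_train, TRUE, seed))
  tr_inan <- unlist(gather(n_train, FALSE, seed + 100003L))
  tr_live <- tr_live[!is.na(tr_live) & tr_live > 0]
  tr_inan <- tr_inan[!is.na(tr_inan)]
  fit <- suppressWarnings(fit_pds(tr_live, tr_inan))

  te_live <- gather(n_test, TRUE, seed + 200003L)
  te_inan <- gather(n_test, FALSE, seed + 300007L)
  eval_class <- function(nus_list, truth) {
    sv <- character(0); st <- character(0)
    av <- character(0); at <- character(0)
    for (nus in nus_list) {
      ok <- !is.na(nus)
      if (any(ok)) {
        sv <- c(sv, classify_liveness(nus[ok], fit$params)$label)
        st <- c(st, rep(truth, sum(ok)))
      }
      if (all(ok)) {
        av <- c(av, classify_accumulated(nus, fit$params)$label)
        at <- c(at, truth)
      }
    }
    list(sv = sv, st = st, av = av, at = at)
  }
  el <- eval_class(te_live, "live")
  ei <- eval_class(te_inan, "inanimate")
  nus <- tibble::tibble(
    truth = c(rep("live", sum(lengths(te_live))),
              rep("inanimate", sum(lengths(te_inan)))),
    nu = c(unlist(te_live), unlist(te_inan)))
  structure(list(
    fit = fit,
    single = error_rates(c(el$st, ei$st), c(el$sv, ei$sv)),
    accumulated = error_rates(c(el$at, ei$at), c(el$av, ei$av)),
    nus = nus),
    class = "liveness_study")
}

#' @export
print.liveness_study <- function(x, ...) {
  cat("Synthetic liveness study\n")
  print(x$fit$params)
  cat("single-window rule:\n"); print(x$single)
  cat("accumulated three-window rule:\n"); print(x$accumulated)
  invisible(x)
}
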