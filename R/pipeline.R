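#' Run the full measurement pipeline on a frame sequence
#'
#' End-to-end orchestration: read frames (or accept a [frame_series()]),
#' resolve the two measurement ROIs, reduce each to an observed brightness
#' series, estimate per-window heart and respiration rates, and classify
#' liveness from the ratio-variation statistic of every cardiac window
#' (plus the accumulated three-window rule when at least three windows 5 s
#' apart are available).
#'
#' @param input Path to a frame directory, or a [frame_series()].
#' @param bvp_roi,resp_roi [roi_rect()]s for the cardiac and respiratory
#'   measurements; alternatively give `face` and `upper_body` boxes and the
#'   ROIs are derived by the 60%/80% rule of [derive_rois()].
#' @param face,upper_body Optional detection boxes ([roi_rect()]).
#' @param species Preset passed to [rate_config()].
#' @param channel `"green"` or `"mono"` (frame-directory input only).
#' @param frame_rate Override when the input carries no frame rate.
#' @param window_s,stride_s Sliding-window geometry in seconds.
#' @param liveness Run the liveness classifier? Default `TRUE`.
#' @param params Liveness density parameters, a [pd_params()].
#' @param out_prefix When given, results are written to
#'   `<out_prefix>_results.csv` and `<out_prefix>_results.json`.
#' @param seed Integer seed controlling the (seeded) FastICA
#'   initializations.
#' @return A tibble with one row per window and kind: `kind`, `window`,
#'   `t_center_s`, `rate_per_min`, `peak_freq_hz`, `peak_ratio`, `nu`,
#'   `liveness_flag`, `flagged`, `note`; the accumulated verdict (if
#'   computed) is in `attr(, "accumulated_verdict")`.
#' @export
run_pipeline <- function(input, bvp_roi = NULL, resp_roi = NULL,
                         face = NULL, upper_body = NULL,
                         species = "human", channel = "green",
                         frame_rate = NULL, window_s = 30, stride_s = 1,
                         liveness = TRUE, params = pd_params(),
                         out_prefix = NULL, seed = 1L) {
  fs <- if (inherits(input, "frame_series")) input
        else read_frames(input, channel = channel, frame_rate = frame_rate)
  if (is.null(bvp_roi) || is.null(resp_roi)) {
    if (is.null(face) || is.null(upper_body)) {
      stop("run_pipeline: give bvp_roi and resp_roi, or face and ",
           "upper_body boxes")
    }
    rois <- derive_rois(face, upper_body)
    if (is.null(bvp_roi)) bvp_roi <- rois$bvp
    if (is.null(resp_roi)) resp_roi <- rois$resp
  }
  duration <- length(fs) / fs$frame_rate
  if (window_s > duration) {
    stop("run_pipeline: window (", window_s, " s) exceeds input duration (",
         signif(duration, 4), " s)")
  }
  cfg_bvp <- rate_config("bvp", species, window_s = window_s,
                         stride_s = stride_s)
  cfg_resp <- rate_config("resp", species, window_s = window_s,
                          stride_s = stride_s)
  bvp_series <- extract_roi_series(fs, bvp_roi, label = "bvp")
  resp_series <- extract_roi_series(fs, resp_roi, label = "resp")
  est_bvp <- dplyr::mutate(
    estimate_vitals(bvp_series, cfg_bvp, seed = seed), kind = "bvp",
    .before = 1L)
  est_resp <- dplyr::mutate(
    estimate_vitals(resp_series, cfg_resp, seed = seed + 5000L),
    kind = "resp", .before = 1L)
  out <- dplyr::bind_rows(est_bvp, est_resp)
  if (liveness) {
    # the reference densities describe the cardiac (5-point-smoothed)
    # chain; respiratory windows are not classified
    verdicts <- rep(NA_character_, nrow(out))
    has_nu <- !is.na(out$nu) & out$kind == "bvp"
    if (any(has_nu)) {
      verdicts[has_nu] <- classify_liveness(out$nu[has_nu], params)$label
    }
    out$liveness_flag <- verdicts
    nus_bvp <- out$nu[out$kind == "bvp" & !is.na(out$nu)]
    if (length(nus_bvp) >= 3L) {
      # three windows spaced ~5 s apart within the available run
      step <- max(1L, as.integer(round(5 / stride_s)))
      pick <- unique(pmin(c(1L, 1L + step, 1L + 2L * step),
                          length(nus_bvp)))
      if (length(pick) == 3L) {
        attr(out, "accumulated_verdict") <-
          classify_accumulated(nus_bvp[pick], params)
      }
    }
  } else {
    out$liveness_flag <- NA_character_
  }
  attr(out, "frame_rate") <- fs$frame_rate
  if (!is.null(out_prefix)) write_results(out, out_prefix)
  out
}

#' Write pipeline results as CSV and JSON
#'
#' @param results Tibble from [run_pipeline()] or [estimate_vitals()].
#' @param out_prefix Path prefix; writes `<prefix>_results.csv` and
#'   `<prefix>_results.json`.
#' @return The two file paths, invisibly.
#' @export
write_results <- function(results, out_prefix) {
  cols <- intersect(c("kind", "window", "t_center_s", "rate_per_min",
                      "peak_freq_hz", "peak_ratio", "nu", "liveness_flag",
                      "flagged", "note"), names(results))
  csv <- paste0(out_prefix, "_results.csv")
  jsn <- paste0(out_prefix, "_results.json")
  utils::write.csv(results[, cols], csv, row.names = FALSE)
  payload <- list(results = results[, cols])
  acc <- attr(results, "accumulated_verdict")
  if (!is.null(acc)) payload$accumulated_verdict <- acc
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = jsn))
}
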