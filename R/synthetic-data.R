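#' Parameters of a synthetic vital-signs scene
#'
#' Describes a simulated single-channel recording of a subject: a
#' quasi-periodic cardiac brightness modulation inside a skin ROI, a
#' quasi-periodic respiratory modulation inside a chest ROI, a slow
#' illumination drift over the whole frame, and additive Gaussian sensor
#' noise, quantized to 8 bits. Defaults emulate a seated adult filmed at
#' 15 fps for 30 s: 72 bpm heart rate, 15 breaths/min respiration,
#' moderate noise.
#'
#' The cardiac waveform is a slightly asymmetric pulse (fundamental plus a
#' 10% second harmonic) rather than a pure sinusoid, so that spectral peak
#' selection is exercised against a realistic non-sinusoidal pulse; the
#' respiratory waveform is sinusoidal. Drift is a sub-0.05 Hz sinusoid.
#'
#' Besides white sensor noise, the scene carries an illumination flicker
#' term: a temporally correlated (AR(1)) brightness fluctuation common to
#' the whole frame, emulating mains-driven and ambient-light flicker in
#' indoor footage. Flicker is what makes inanimate recordings wideband but
#' low-frequency-dominated, the regime in which the ratio-variation
#' statistic of a no-signal scene concentrates around 0.5 rather than
#' scattering uniformly.
#'
#' @param frame_rate Frames per second (must exceed twice `hr_freq`).
#' @param duration Recording length in seconds.
#' @param hr_freq Cardiac fundamental in Hz (must exceed `rr_freq`).
#' @param rr_freq Respiratory fundamental in Hz (positive).
#' @param cardiac_amp,resp_amp Modulation amplitudes in brightness units.
#' @param drift_amp Illumination drift amplitude in brightness units.
#' @param drift_period Drift period in seconds (at least 20 s).
#' @param noise_sd Additive white Gaussian sensor-noise SD in brightness
#'   units.
#' @param flicker_sd SD of the AR(1) illumination-flicker term in
#'   brightness units (0 disables it).
#' @param flicker_phi Lag-one autocorrelation of the flicker term in
#'   `[0, 1)`; the default 0.85 at 15 fps concentrates flicker below about
#'   0.4 Hz.
#' @param baseline Mean brightness (0-255).
#' @param frame_shape `c(height, width)` in pixels.
#' @param skin_roi,chest_roi Non-overlapping [roi_rect()]s inside the frame.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   bit-identical.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(frame_rate = 15, duration = 30,
                         hr_freq = 1.2, rr_freq = 0.25,
                         cardiac_amp = 3, resp_amp = 3,
                         drift_amp = 5, drift_period = 30,
                         noise_sd = 1, flicker_sd = 2, flicker_phi = 0.85,
                         baseline = 128,
                         frame_shape = c(64, 64),
                         skin_roi = roi_rect(20, 8, 24, 20),
                         chest_roi = roi_rect(12, 40, 40, 16),
                         seed = 1L) {
  if (!(hr_freq > rr_freq && rr_freq > 0)) {
    stop("scene_params: need hr_freq > rr_freq > 0")
  }
  if (frame_rate <= 2 * hr_freq) {
    stop("scene_params: frame_rate must exceed twice hr_freq (Nyquist)")
  }
  if (baseline < 0 || baseline > 255) stop("scene_params: baseline outside 0-255")
  if (flicker_sd < 0 || flicker_phi < 0 || flicker_phi >= 1) {
    stop("scene_params: need flicker_sd >= 0 and flicker_phi in [0, 1)")
  }
  if (drift_period < 20) {
    stop("scene_params: drift_period under 20 s is not a slow drift")
  }
  if (baseline + cardiac_amp * 1.1 + resp_amp + drift_amp > 255 ||
      baseline - cardiac_amp * 1.1 - resp_amp - drift_amp < 0) {
    warning("scene_params: components can clip at the 8-bit limits")
  }
  structure(list(frame_rate = frame_rate, duration = duration,
                 hr_freq = hr_freq, rr_freq = rr_freq,
                 cardiac_amp = cardiac_amp, resp_amp = resp_amp,
                 drift_amp = drift_amp, drift_period = drift_period,
                 noise_sd = noise_sd, flicker_sd = flicker_sd,
                 flicker_phi = flicker_phi, baseline = baseline,
                 frame_shape = as.integer(frame_shape),
                 skin_roi = skin_roi, chest_roi = chest_roi,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# phases are drawn first, in fixed order, from the scene seed, so the 1-D
# series and the frame sequence built from the same params share them
scene_phases <- function(params) {
  ph <- withr::with_seed(params$seed, stats::runif(3, 0, 2 * pi))
  list(cardiac = ph[1], resp = ph[2], drift = ph[3])
}

scene_components <- function(params) {
  n <- round(params$duration * params$frame_rate)
  t <- (seq_len(n) - 1) / params$frame_rate
  ph <- scene_phases(params)
  list(
    t = t, n = n,
    cardiac = params$cardiac_amp *
      (sin(2 * pi * params$hr_freq * t + ph$cardiac) +
         0.1 * sin(4 * pi * params$hr_freq * t + 2 * ph$cardiac)),
    resp = params$resp_amp * sin(2 * pi * params$rr_freq * t + ph$resp),
    drift = params$drift_amp *
      sin(2 * pi * t / params$drift_period + ph$drift),
    flicker = if (params$flicker_sd > 0) {
      # stationary AR(1), shared by every pixel (global illumination)
      withr::with_seed(params$seed + 4L, {
        e <- stats::rnorm(n, 0,
                          params$flicker_sd * sqrt(1 - params$flicker_phi^2))
        as.numeric(stats::filter(e, params$flicker_phi,
                                 method = "recursive"))
      })
    } else rep(0, n))
}

#' Generate a 1-D observed brightness series with known ground truth
#'
#' The cardiac series is baseline + asymmetric pulse + drift + noise; the
#' respiratory series is baseline + sinusoid + drift + noise. Deterministic
#' per `params$seed`.
#'
#' @param params A [scene_params()].
#' @param which `"cardiac"` or `"respiratory"`.
#' @return An [observed_series()] of length
#'   `round(duration * frame_rate)`, labelled `"bvp"` or `"resp"`.
#' @export
generate_vital_series <- function(params,
                                  which = c("cardiac", "respiratory")) {
  which <- match.arg(which)
  stopifnot(inherits(params, "scene_params"))
  comp <- scene_components(params)
  signal <- if (which == "cardiac") comp$cardiac else comp$resp
  noise <- withr::with_seed(
    params$seed + if (which == "cardiac") 1L else 2L,
    stats::rnorm(comp$n, 0, params$noise_sd))
  observed_series(params$baseline + signal + comp$drift + comp$flicker +
                    noise,
                  params$frame_rate,
                  label = if (which == "cardiac") "bvp" else "resp")
}

#' Generate a synthetic frame sequence
#'
#' Every pixel carries baseline, drift, global flicker and independent
#' Gaussian sensor noise;
#' pixels inside the skin ROI additionally carry the cardiac modulation and
#' pixels inside the chest ROI the respiratory modulation. Frames are
#' rounded to integers and clipped to 0-255 (8-bit capture).
#'
#' @param params A [scene_params()]; skin and chest ROIs must not overlap.
#' @return A [frame_series()].
#' @export
generate_frame_sequence <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$frame_shape[1]; w <- params$frame_shape[2]
  if (!rect_inside(params$skin_roi, h, w) ||
      !rect_inside(params$chest_roi, h, w)) {
    stop("generate_frame_sequence: ROI outside the frame")
  }
  if (rects_overlap(params$skin_roi, params$chest_roi)) {
    stop("generate_frame_sequence: skin and chest ROIs overlap")
  }
  comp <- scene_components(params)
  sr <- params$skin_roi; cr <- params$chest_roi
  s_rows <- (sr$y + 1L):(sr$y + sr$height)
  s_cols <- (sr$x + 1L):(sr$x + sr$width)
  c_rows <- (cr$y + 1L):(cr$y + cr$height)
  c_cols <- (cr$x + 1L):(cr$x + cr$width)
  frames <- withr::with_seed(params$seed + 3L, lapply(seq_len(comp$n),
    function(j) {
      m <- matrix(params$baseline + comp$drift[j] + comp$flicker[j] +
                    stats::rnorm(h * w, 0, params$noise_sd), h, w)
      m[s_rows, s_cols] <- m[s_rows, s_cols] + comp$cardiac[j]
      m[c_rows, c_cols] <- m[c_rows, c_cols] + comp$resp[j]
      pmin(pmax(round(m), 0), 255)
    }))
  frame_series(frames, params$frame_rate, channel = "mono")
}

#' Generate an inanimate (no vital signs) frame sequence
#'
#' Drift and noise only: the scene of a photograph, drawing or mannequin.
#' Cardiac and respiratory amplitudes are forced to zero; everything else
#' follows [generate_frame_sequence()].
#'
#' @param params A [scene_params()].
#' @return A [frame_series()] with no periodic component beyond the noise
#'   floor in 0-8 Hz.
#' @export
generate_inanimate_sequence <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  params$cardiac_amp <- 0
  params$resp_amp <- 0
  generate_frame_sequence(params)
}

#' Write a synthetic scene to disk with its ground-truth manifest
#'
#' Renders the frame sequence and writes it as a directory of frames plus a
#' `manifest.json` recording the true rates, seed and parameters, so a
#' recovery run can be scored against the truth.
#'
#' @param params A [scene_params()].
#' @param dir Output directory.
#' @param format `"pgm"` or `"png"`.
#' @param inanimate Render the inanimate control instead?
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(params, dir, format = c("pgm", "png"),
                         inanimate = FALSE) {
  stopifnot(inherits(params, "scene_params"))
  fs <- if (inanimate) generate_inanimate_sequence(params)
        else generate_frame_sequence(params)
  plain <- unclass(params)
  plain$skin_roi <- unclass(plain$skin_roi)
  plain$chest_roi <- unclass(plain$chest_roi)
  write_frames(fs, dir, format = format,
               manifest = list(hr_bpm = params$hr_freq * 60,
                               rr_bpm = params$rr_freq * 60,
                               seed = params$seed,
                               inanimate = inanimate,
                               params = plain))
  invisible(dir)
}
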