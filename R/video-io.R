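#' Rectangular region of interest
#'
#' Pixel rectangles use 0-based, half-open integer geometry: a rectangle
#' covers columns `[x, x + width)` and rows `[y, y + height)`.
#'
#' @param x,y Top-left corner in pixels (0-based).
#' @param width,height Extent in pixels; both must be positive.
#' @return An object of class `roi_rect`.
#' @examples
#' roi_rect(10, 20, 64, 48)
#' @export
roi_rect <- function(x, y, width, height) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(width), is.numeric(height))
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (x < 0L || y < 0L) stop("roi_rect: x and y must be non-negative")
  if (width <= 0L || height <= 0L) {
    stop("roi_rect: width and height must be positive")
  }
  structure(list(x = x, y = y, width = width, height = height),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect %dx%d at (%d, %d)>\n", x$width, x$height, x$x, x$y))
  invisible(x)
}

rect_inside <- function(roi, n_rows, n_cols) {
  roi$x >= 0L && roi$y >= 0L &&
    roi$x + roi$width <= n_cols && roi$y + roi$height <= n_rows
}

rects_overlap <- function(a, b) {
  a$x < b$x + b$width && b$x < a$x + a$width &&
    a$y < b$y + b$height && b$y < a$y + a$height
}

#' Ordered single-channel frame sequence
#'
#' @param frames List of numeric matrices (brightness, nominally 0-255), all
#'   of identical dimensions; matrices are indexed `[row, col]` so `nrow` is
#'   image height.
#' @param frame_rate Sampling rate in frames per second; must be positive.
#' @param channel Channel label, `"green"` or `"mono"`.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_rate, channel = c("mono", "green")) {
  channel <- match.arg(channel)
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frame_series: 'frames' must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("frame_series: every frame must be a matrix")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frame_series: all frames must share the same dimensions")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_series: frame_rate must be a single positive number")
  }
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate),
                 channel = channel),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_series: %d frames of %dx%d px, %.3g fps, channel=%s>\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$channel))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

#' One-dimensional observed brightness series
#'
#' The spatially averaged ROI brightness, one sample per frame. Carries its
#' sampling rate so downstream spectral stages need no extra bookkeeping.
#'
#' @param values Numeric vector of brightness samples; length at least 2,
#'   all finite.
#' @param frame_rate Sampling rate in Hz.
#' @param roi Optional `roi_rect` the series was averaged over.
#' @param label Optional label, e.g. `"bvp"` or `"resp"`.
#' @return A numeric vector of class `observed_series` with attributes
#'   `frame_rate`, `roi` and `label`.
#' @export
observed_series <- function(values, frame_rate, roi = NULL, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("observed_series: need at least 2 samples")
  if (!all(is.finite(values))) stop("observed_series: values must be finite")
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("observed_series: frame_rate must be positive")
  }
  structure(values, frame_rate = as.numeric(frame_rate), roi = roi,
            label = label, class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series: %d samples @ %.3g Hz%s>\n",
              length(x), attr(x, "frame_rate"),
              if (is.null(attr(x, "label"))) "" else
                paste0(", ", attr(x, "label"))))
  utils::str(as.numeric(x))
  invisible(x)
}

series_rate <- function(x, frame_rate = NULL) {
  if (!is.null(frame_rate)) return(frame_rate)
  fr <- attr(x, "frame_rate")
  if (is.null(fr)) stop("frame_rate is required when input carries none")
  fr
}

# keeps class/attrs when a transformation preserves sampling
rewrap_series <- function(values, template) {
  structure(as.numeric(values),
            frame_rate = attr(template, "frame_rate"),
            roi = attr(template, "roi"),
            label = attr(template, "label"),
            class = "observed_series")
}

## ---- PGM read/write (no installed R package parses PGM) ----

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a PGM file: ", path)
  # header tokens: width height maxval, with '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("read_pgm: truncated header in ", path)
    if (ch == "#") { # skip to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (maxval > 255L) stop("read_pgm: only 8-bit PGM supported")
  if (magic == "P5") {
    raw_px <- readBin(con, "raw", n = w * h)
    px <- as.integer(raw_px)
  } else {
    px <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(px) != w * h) stop("read_pgm: truncated pixel data in ", path)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(mat, path, ascii = TRUE) {
  mat <- pmin(pmax(round(mat), 0), 255)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mat), nrow(mat)), "255"), con)
    writeLines(apply(mat, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", ncol(mat), " ", nrow(mat), "\n255\n"), con,
              eos = NULL)
    writeBin(as.raw(t(mat)), con)
  }
  invisible(path)
}

## ---- frame directory I/O ----

#' Read a frame sequence from a directory of image files
#'
#' Reads all `.pgm` / `.png` files in `path` in lexicographic order and
#' extracts the working channel. RGB PNG input with `channel = "green"`
#' returns the green plane; mono input requested as green falls back to the
#' sole plane with a warning. The frame rate is taken from a `manifest.json`
#' in the directory (field `frame_rate`) unless overridden.
#'
#' @param path Directory containing the frames.
#' @param channel `"green"` or `"mono"`.
#' @param frame_rate Optional explicit frame rate (Hz); overrides the
#'   manifest.
#' @return A [frame_series()].
#' @export
read_frames <- function(path, channel = c("green", "mono"),
                        frame_rate = NULL) {
  channel <- match.arg(channel)
  if (!dir.exists(path)) stop("read_frames: no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(pgm|png)$", full.names = TRUE))
  if (length(files) == 0L) stop("read_frames: no frames found in ", path)
  if (is.null(frame_rate)) {
    mf <- file.path(path, "manifest.json")
    if (file.exists(mf)) {
      manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
      frame_rate <- manifest$frame_rate
    }
  }
  if (is.null(frame_rate)) {
    stop("read_frames: frame rate not in manifest and no override given")
  }
  mono_fallback <- FALSE
  frames <- lapply(files, function(f) {
    if (grepl("\\.png$", f)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) {
        plane <- if (channel == "green") img[, , 2] else img[, , 1]
      } else {
        if (channel == "green") mono_fallback <<- TRUE
        plane <- img
      }
      plane * 255
    } else {
      if (channel == "green") mono_fallback <<- TRUE
      read_pgm(f) * 1.0
    }
  })
  if (mono_fallback && channel == "green") {
    warning("read_frames: input is single-plane; using it as the working ",
            "channel in place of green")
  }
  frame_series(frames, frame_rate,
               channel = if (channel == "green" && !mono_fallback) "green"
               else "mono")
}

#' Write a frame sequence to a directory with a ground-truth manifest
#'
#' @param fs A [frame_series()].
#' @param dir Output directory (created if needed).
#' @param format `"pgm"` (portable graymap, ASCII) or `"png"`.
#' @param manifest Named list merged into `manifest.json` alongside
#'   `frame_rate` and `n_frames`.
#' @return `dir`, invisibly.
#' @export
write_frames <- function(fs, dir, format = c("pgm", "png"),
                         manifest = list()) {
  format <- match.arg(format)
  stopifnot(inherits(fs, "frame_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(fs$frames)
  fmt <- paste0("frame_%0", max(4L, nchar(n)), "d.", format)
  for (i in seq_len(n)) {
    f <- file.path(dir, sprintf(fmt, i))
    if (format == "pgm") {
      write_pgm(fs$frames[[i]], f)
    } else {
      png::writePNG(pmin(pmax(fs$frames[[i]], 0), 255) / 255, f)
    }
  }
  info <- c(list(frame_rate = fs$frame_rate, n_frames = n,
                 channel = fs$channel), manifest)
  jsonlite::write_json(info, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Derive measurement ROIs from face and upper-body boxes
#'
#' The cardiac (BVP) ROI is the centered sub-rectangle of the face covering
#' 60% of its width and 80% of its height. The respiratory ROI is the band
#' between the bottom of the face and the bottom of the upper body, 80% of
#' the upper-body width, horizontally centered on the upper body.
#'
#' @param face,upper_body `roi_rect` detections (manual or from a cascade
#'   detector).
#' @return A list with elements `bvp` and `resp`, both `roi_rect`.
#' @examples
#' derive_rois(roi_rect(100, 100, 100, 120), roi_rect(50, 80, 200, 300))
#' @export
derive_rois <- function(face, upper_body) {
  stopifnot(inherits(face, "roi_rect"), inherits(upper_body, "roi_rect"))
  bw <- as.integer(floor(0.60 * face$width))
  bh <- as.integer(floor(0.80 * face$height))
  if (bw <= 0L || bh <= 0L) stop("derive_rois: face box too small")
  bvp <- roi_rect(face$x + (face$width - bw) %/% 2L,
                  face$y + (face$height - bh) %/% 2L, bw, bh)
  chest_top <- face$y + face$height
  chest_bottom <- upper_body$y + upper_body$height
  if (chest_bottom <= chest_top) {
    stop("derive_rois: face bottom at or below upper-body bottom; ",
         "no chest band available")
  }
  rw <- as.integer(floor(0.80 * upper_body$width))
  if (rw <= 0L) stop("derive_rois: upper-body box too small")
  resp <- roi_rect(upper_body$x + (upper_body$width - rw) %/% 2L,
                   chest_top, rw, chest_bottom - chest_top)
  list(bvp = bvp, resp = resp)
}

#' Reduce a frame sequence to one observed sample per frame
#'
#' @param fs A [frame_series()].
#' @param roi A [roi_rect()] fully inside the frames.
#' @param label Optional label attached to the series.
#' @return An [observed_series()] of length `length(fs)`: the arithmetic
#'   mean of pixel intensities inside `roi`, per frame.
#' @export
extract_roi_series <- function(fs, roi, label = NULL) {
  stopifnot(inherits(fs, "frame_series"), inherits(roi, "roi_rect"))
  d <- dim(fs$frames[[1]])
  if (!rect_inside(roi, d[1], d[2])) {
    stop("extract_roi_series: roi extends outside the frames")
  }
  rows <- (roi$y + 1L):(roi$y + roi$height)
  cols <- (roi$x + 1L):(roi$x + roi$width)
  vals <- vapply(fs$frames, function(m) mean(m[rows, cols]), numeric(1))
  observed_series(vals, fs$frame_rate, roi = roi, label = label)
}
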