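test_that("roi_rect validates its geometry", {
  r <- roi_rect(10, 20, 30, 40)
  expect_s3_class(r, "roi_rect")
  expect_error(roi_rect(0, 0, 0, 10), "positive")
  expect_error(roi_rect(0, 0, 10, 0), "positive")
  expect_error(roi_rect(-1, 0, 5, 5), "non-negative")
})

test_that("derive_rois applies the 60%/80% face rule and the chest band", {
  rois <- derive_rois(roi_rect(100, 100, 100, 120), roi_rect(50, 80, 200, 300))
  expect_equal(unclass(rois$bvp)[c("x", "y", "width", "height")],
               list(x = 120L, y = 112L, width = 60L, height = 96L))
  # chest band spans face bottom to body bottom, 80% of body width centered
  expect_equal(rois$resp$y, 100L + 120L)
  expect_equal(rois$resp$y + rois$resp$height, 80L + 300L)
  expect_equal(rois$resp$width, 160L)
  expect_equal(rois$resp$x, 70L)
})

test_that("derive_rois rejects degenerate boxes", {
  expect_error(roi_rect(100, 100, 100, 0), "positive")
  # face bottom at/below the upper-body bottom leaves no chest band
  expect_error(derive_rois(roi_rect(60, 100, 100, 280),
                           roi_rect(50, 80, 200, 300)), "chest band")
})

test_that("extract_roi_series averages the ROI and conserves frame count", {
  frames <- replicate(7, matrix(50, 12, 10), simplify = FALSE)
  fs <- frame_series(frames, 15)
  s <- extract_roi_series(fs, roi_rect(2, 3, 4, 5))
  expect_length(s, 7L)
  expect_true(all(as.numeric(s) == 50))

  # 1x1 roi follows the single pixel
  frames2 <- lapply(1:5, function(i) {
    m <- matrix(0, 4, 4); m[2, 3] <- i; m
  })
  s2 <- extract_roi_series(frame_series(frames2, 10), roi_rect(2, 1, 1, 1))
  expect_equal(as.numeric(s2), as.numeric(1:5))

  expect_error(extract_roi_series(fs, roi_rect(8, 3, 4, 5)), "outside")
})

test_that("ROI averaging is linear and permutation invariant", {
  set.seed(42)
  base <- lapply(1:6, function(i) matrix(runif(48, 0, 255), 6, 8))
  other <- lapply(1:6, function(i) matrix(runif(48, 0, 255), 6, 8))
  roi <- roi_rect(1, 2, 5, 3)
  mix <- Map(function(a, b) 2 * a + 3 * b, base, other)
  s_mix <- extract_roi_series(frame_series(mix, 15), roi)
  s_a <- extract_roi_series(frame_series(base, 15), roi)
  s_b <- extract_roi_series(frame_series(other, 15), roi)
  expect_equal(as.numeric(s_mix), 2 * as.numeric(s_a) + 3 * as.numeric(s_b))

  # shuffling pixels inside the ROI leaves the mean unchanged
  set.seed(1)
  shuffled <- lapply(base, function(m) {
    rows <- 3:5; cols <- 2:6
    vals <- as.numeric(m[rows, cols])
    m[rows, cols] <- matrix(sample(vals), length(rows), length(cols))
    m
  })
  s_shuf <- extract_roi_series(frame_series(shuffled, 15), roi)
  expect_equal(as.numeric(s_shuf), as.numeric(s_a))
})

test_that("PGM frames round-trip through a directory with a manifest", {
  p <- scene_params(duration = 1, frame_rate = 8, hr_freq = 1.2,
                    frame_shape = c(16, 16),
                    skin_roi = roi_rect(1, 1, 6, 6),
                    chest_roi = roi_rect(8, 8, 6, 6), seed = 5)
  fs <- generate_frame_sequence(p)
  dir <- withr::local_tempdir()
  write_frames(fs, dir, format = "pgm", manifest = list(hr_bpm = 72))
  back <- read_frames(dir, channel = "mono")
  expect_length(back, length(fs))
  expect_equal(dim(back$frames[[1]]), dim(fs$frames[[1]]))
  expect_equal(back$frames[[3]], fs$frames[[3]])
  expect_equal(back$frame_rate, 8)
})

test_that("green channel extraction takes the G plane of RGB input", {
  dir <- withr::local_tempdir()
  set.seed(3)
  img <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
  img <- round(img * 255) / 255      # representable exactly in 8-bit PNG
  png::writePNG(img, file.path(dir, "frame_0001.png"))
  fs <- read_frames(dir, channel = "green", frame_rate = 15)
  expect_equal(fs$frames[[1]], img[, , 2] * 255, tolerance = 1e-12)
  expect_identical(fs$channel, "green")
})

test_that("mono input requested as green falls back with a warning", {
  dir <- withr::local_tempdir()
  write_pgm_mat <- matrix(128, 8, 8)
  vitalcam:::write_pgm(write_pgm_mat, file.path(dir, "frame_0001.pgm"))
  expect_warning(fs <- read_frames(dir, channel = "green", frame_rate = 15),
                 "single-plane")
  expect_identical(fs$channel, "mono")
})

test_that("read_frames reports missing inputs", {
  expect_error(read_frames(file.path(tempdir(), "nope-123")), "no such")
  empty <- withr::local_tempdir()
  expect_error(read_frames(empty, frame_rate = 15), "no frames")
  dir <- withr::local_tempdir()
  vitalcam:::write_pgm(matrix(1, 4, 4), file.path(dir, "frame_0001.pgm"))
  expect_error(read_frames(dir, channel = "mono"), "frame rate")
})
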