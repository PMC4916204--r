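make_const_frames <- function(n, h = 32, w = 32, val = 0.5) {
  frame_sequence(replicate(n, array(val, dim = c(h, w)), simplify = FALSE), 30)
}

test_that("trace extraction is the active-minus-reference region mean", {
  roi <- roi_spec(active = c(16, 8, 3), reference = c(16, 24, 3))
  fr <- make_const_frames(10)
  # constant frames: trace is the constant difference (here zero)
  tr <- extract_trace(fr, roi)
  expect_equal(tr$values, rep(0, 10))
  expect_equal(tr$sample_rate, 30)

  # known offset between regions
  f <- array(0.2, dim = c(32, 32)); f[, 1:16] <- 0.7
  fr2 <- frame_sequence(replicate(5, f, simplify = FALSE), 30)
  tr2 <- extract_trace(fr2, roi)
  expect_equal(tr2$values, rep(0.5, 5))

  expect_error(extract_trace(fr, roi_spec(c(2, 2, 5), c(16, 24, 3))), "outside")
  expect_error(extract_trace(fr, roi_spec(c(16, 10, 3), c(16, 12, 3))), "disjoint")
})

test_that("extraction is linear in intensity and cancels uniform offsets", {
  b <- make_beat_train(80, duration_s = 5)
  sv <- make_video(b, video_scene(background_noise_sd = 0), duration_s = 5)
  tr <- extract_trace(sv$frames, sv$roi)

  scaled <- frame_sequence(lapply(sv$frames$frames, function(f) 3 * f), 60)
  expect_equal(extract_trace(scaled, sv$roi)$values, 3 * tr$values,
               tolerance = 1e-12)

  # a spatially uniform, time-varying illumination drift cancels out
  drift <- frame_sequence(mapply(function(f, d) f + d, sv$frames$frames,
                                 sin(seq_len(length(sv$frames$frames)) / 10),
                                 SIMPLIFY = FALSE), 60)
  expect_equal(extract_trace(drift, sv$roi)$values, tr$values,
               tolerance = 1e-12)
})

test_that("a pulsing video yields a trace with the pulse's Fourier peak", {
  # 80 beats/min = 1.333 Hz
  b <- make_beat_train(80, duration_s = 30)
  sv <- make_video(b, video_scene(background_noise_sd = 0.01), duration_s = 30,
                   seed = 4)
  tr <- extract_trace(sv$frames, sv$roi)
  v <- tr$values - mean(tr$values)
  sp <- Mod(fft(v))^2
  freqs <- (seq_along(v) - 1) / length(v) * tr$sample_rate
  sel <- freqs > 0.2 & freqs < tr$sample_rate / 2
  peak <- freqs[sel][which.max(sp[sel])]
  expect_lt(abs(peak - 80 / 60), 0.05)
})

test_that("trace CSV round-trips and rejects malformed time axes", {
  toy <- tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0.0,1.0", "0.1,2.0", "0.2,1.0"), toy)
  tr <- load_trace(toy)
  expect_equal(tr$values, c(1, 2, 1))
  expect_equal(tr$sample_rate, 10)

  set.seed(8)
  x <- contraction_trace(rnorm(1000), 60, t0 = 2.5)
  path <- tempfile(fileext = ".csv")
  save_trace(x, path)
  y <- load_trace(path)
  expect_equal(y$values, x$values)
  expect_equal(y$sample_rate, x$sample_rate)
  expect_equal(y$t0, x$t0)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0.0,1", "0.2,2", "0.1,3"), bad)
  expect_error(load_trace(bad), "row 3")
  uneven <- tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0.0,1", "0.1,2", "0.3,3"), uneven)
  expect_error(load_trace(uneven), "uniformly")
})

test_that("ROI specifications load from YAML config", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("active: {row: 16, col: 8, radius: 3}",
               "reference: {row: 16, col: 24, radius: 3}",
               "channel_weights: [1, 0, 0]"), cfg)
  roi <- load_roi(cfg)
  expect_equal(roi$active, c(16, 8, 3))
  expect_equal(roi$channel_weights, c(1, 0, 0))
  bad <- tempfile(fileext = ".yaml")
  writeLines("active: {row: 1}", bad)
  expect_error(load_roi(bad), "ROI config")
})

test_that("frames round-trip through PNG directories and multi-page TIFF", {
  b <- make_beat_train(80, duration_s = 1)
  sv <- make_video(b, video_scene(frame_size = c(48, 48), heart_center = c(24, 21),
                                  heart_radius = 5, shell_center = c(24, 24),
                                  shell_axes = c(17, 14), reference_point = c(4, 44),
                                  background_noise_sd = 0),
                   duration_s = 1)
  dir_png <- tempfile()
  write_frames(sv$frames, dir_png)
  back <- read_frames(dir_png, 60)
  expect_length(back$frames, 60)
  # 8-bit quantisation on write
  expect_equal(back$frames[[1]], sv$frames$frames[[1]], tolerance = 1 / 255)

  tif <- tempfile(fileext = ".tif")
  write_frames(sv$frames, tif)
  back2 <- read_frames(tif, 60)
  expect_length(back2$frames, 60)
  expect_equal(back2$frames[[10]], sv$frames$frames[[10]], tolerance = 1 / 255)
})
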