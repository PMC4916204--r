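test_that("beat trains follow their generating rate deterministically", {
  b <- make_beat_train(80, duration_s = 60)
  expect_length(b$event_times, 80)
  expect_equal(diff(b$event_times), rep(0.75, 79), tolerance = 1e-12)

  expect_length(make_beat_train(0, duration_s = 60)$event_times, 0)

  steps <- data.frame(start_s = c(0, 30), end_s = c(30, 60), hr_bpm = c(60, 0))
  b2 <- make_beat_train(steps)
  expect_length(b2$event_times, 30)
  expect_true(all(b2$event_times <= 30 + 1e-9))

  expect_error(make_beat_train(80, duration_s = 10, jitter_sd_ms = -1), "jitter")
  expect_error(make_beat_train(-5, duration_s = 10), "non-negative")
})

test_that("jittered beat trains keep the generating mean interval", {
  mean_ibis <- vapply(1:20, function(s) {
    b <- make_beat_train(60, duration_s = 600, jitter_sd_ms = 20, seed = s)
    mean(diff(b$event_times)) * 1000
  }, numeric(1))
  expect_true(all(abs(mean_ibis - 1000) < 5))
})

test_that("event counts track the rate integral over replicates", {
  r <- 70
  counts <- vapply(1:50, function(s) {
    length(make_beat_train(r, duration_s = 600, jitter_sd_ms = 30,
                           seed = 1000 + s)$event_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10 * r) / (10 * r), 0.02)
})

test_that("generation is deterministic under a fixed seed and restores RNG state", {
  set.seed(99)
  before <- .Random.seed
  b1 <- make_beat_train(70, duration_s = 120, jitter_sd_ms = 15, seed = 5)
  expect_identical(before, .Random.seed)
  b2 <- make_beat_train(70, duration_s = 120, jitter_sd_ms = 15, seed = 5)
  expect_identical(b1, b2)

  c1 <- make_cohort(seed = 11)
  c2 <- make_cohort(seed = 11)
  expect_identical(c1, c2)
})

test_that("rendered video pulses at the ground-truth beats", {
  scene <- video_scene(background_noise_sd = 0)
  still <- make_video(beat_series(numeric(0)), scene, duration_s = 0.5)
  expect_true(all(vapply(still$frames$frames,
                         function(f) identical(f, still$frames$frames[[1]]),
                         logical(1))))

  one <- make_video(beat_series(1), scene, duration_s = 2)
  tr <- extract_trace(one$frames, one$roi)
  v <- tr$values
  local_max <- which(diff(sign(diff(v))) == -2) + 1L
  local_max <- local_max[v[local_max] > min(v) + 0.5 * diff(range(v))]
  expect_length(local_max, 1)
  expect_lt(abs(trace_times(tr)[local_max] - 1), 0.1 + 1e-9)

  expect_error(make_video(beat_series(5), scene, duration_s = 2), "cover")
  expect_error(video_scene(reference_point = c(64, 64)), "outside")
  expect_error(video_scene(heart_center = c(64, 95), heart_radius = 10), "inside")
})

test_that("noise-free cohorts reproduce the linear HR model exactly", {
  cfg <- cohort_config(intercept_sd = 0, ibi_jitter_sd_at_22c = 0,
                       ibi_jitter_growth = 0,
                       arrest_threshold_mean = c(Ta10 = -999, Ta22 = -999),
                       arrest_threshold_sd = c(Ta10 = 0, Ta22 = 0),
                       hr_intercept_22c = c(Ta10 = 78.6, Ta22 = 83.2),
                       hr_slope_cooling = c(Ta10 = 5.1, Ta22 = 7.3))
  co <- make_cohort(cfg, seed = 1)
  seg <- co$segments
  expected <- pmax(cfg$hr_intercept_22c[seg$group] +
                     cfg$hr_slope_cooling[seg$group] * (seg$set_point_c - 22), 0)
  active <- !seg$asystole
  expect_true(all(abs(seg$hr_active[active] - expected[active]) < 1e-6))
  # segments where the linear model hits zero have no beats at all
  expect_true(all(seg$beat_count[expected == 0] <= cfg$residual_beats_max))
})

test_that("arrest thresholds control asystole prevalence at the trough", {
  cfg <- cohort_config(arrest_threshold_mean = c(Ta10 = -999, Ta22 = 13),
                       arrest_threshold_sd = c(Ta10 = 0, Ta22 = 0))
  co <- make_cohort(cfg, seed = 2)
  seg <- co$segments
  at10 <- seg[seg$set_point_c == 10, ]
  expect_true(all(at10$asystole[at10$group == "Ta22"]))
  at22 <- seg[seg$set_point_c == 22 & seg$phase == "cooling", ]
  expect_false(any(at22$asystole[at22$group == "Ta22"]))
})

test_that("asystole is monotone in temperature during cooling (noise-free)", {
  cfg <- cohort_config(intercept_sd = 0, ibi_jitter_sd_at_22c = 0,
                       ibi_jitter_growth = 0)
  co <- make_cohort(cfg, seed = 3)
  seg <- co$segments[co$segments$phase == "cooling", ]
  for (id in unique(seg$spat_id)) {
    s <- seg[seg$spat_id == id, ]
    s <- s[order(-s$set_point_c), ]
    # once asystolic while cooling, asystolic at every colder set-point
    expect_true(all(diff(as.integer(s$asystole)) >= 0))
  }
})

test_that("the default protocol is 13 steps of 600 s from 22 to 10 and back", {
  p <- ramp_protocol()
  expect_equal(nrow(p$steps), 13)
  expect_equal(p$steps$set_point_c, c(seq(22, 10, -2), seq(12, 22, 2)))
  expect_equal(unique(p$steps$end_s - p$steps$start_s), 600)
  expect_equal(p$steps$phase[p$steps$set_point_c == 10], "cooling")
  expect_equal(sum(p$steps$phase == "warming"), 6)
})
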