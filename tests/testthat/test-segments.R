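test_that("an ideal ramp record yields 13 full 600 s segments", {
  p <- ramp_protocol()
  temp <- simulate_temp_trace(p)
  w <- segment_ramp(temp, p)
  expect_equal(nrow(w), 13)
  expect_true(all(w$usable))
  expect_equal(w$end_s - w$start_s, rep(600, 13))
  expect_equal(w$set_point_c, p$steps$set_point_c)
})

test_that("settling lag shortens windows without moving set-points", {
  p <- ramp_protocol(settle_s = 80)
  temp <- simulate_temp_trace(p)
  w <- segment_ramp(temp, p)
  # first step starts at its set-point; later steps settle to within 1 C
  # of a 2 C step after half the 80 s relaxation
  expect_equal(w$end_s[1] - w$start_s[1], 600)
  expect_true(all(abs((w$end_s - w$start_s)[-1] - 560) <= 1.5))
  expect_equal(w$set_point_c, p$steps$set_point_c)

  single <- ramp_protocol(t_start = 22, t_trough = 22)
  ws <- segment_ramp(simulate_temp_trace(single), single)
  expect_equal(nrow(ws), 1)
  expect_equal(ws$end_s - ws$start_s, 600)
})

test_that("a step that never settles is flagged unusable, others survive", {
  p <- ramp_protocol()
  temp <- simulate_temp_trace(p)
  bad <- temp$time_s >= 1200 & temp$time_s < 1800  # third step reads 5 C off
  temp$celsius[bad] <- temp$celsius[bad] + 5
  w <- segment_ramp(temp, p)
  expect_false(w$usable[3])
  expect_true(all(w$usable[-3]))
})

test_that("the asystole rule is a strict sub-45-per-10-min count", {
  expect_true(classify_asystole(44, 600))
  expect_false(classify_asystole(45, 600))
  expect_true(classify_asystole(0, 600))
  # scaling consistency: half the window, half the beats
  expect_equal(classify_asystole(22, 300), classify_asystole(44, 600))
  expect_equal(classify_asystole(23, 300), classify_asystole(46, 600))
})

test_that("segment HR honours both asystole conventions", {
  b <- make_beat_train(80, duration_s = 600)
  ib <- compute_ibi(b)
  asys <- classify_asystole(length(b$event_times), 600)
  expect_false(asys)
  expect_equal(segment_hr(ib, asys, "active_only"), 80, tolerance = 1e-9)
  expect_equal(segment_hr(ib, asys, "zeroed"), 80, tolerance = 1e-9)

  # sporadic 10 beats in 600 s: raw rate 1 beat/min but the segment is
  # asystolic, so the zeroed convention reports 0
  sparse <- make_beat_train(1, duration_s = 600)
  expect_length(sparse$event_times, 10)
  asys2 <- classify_asystole(10, 600)
  expect_true(asys2)
  expect_equal(segment_hr(compute_ibi(sparse), asys2, "zeroed"), 0)
  expect_true(is.na(segment_hr(compute_ibi(sparse), asys2, "active_only")))
})

test_that("Q10 follows the rate-ratio power law", {
  expect_equal(compute_q10(80, 22, 40, 12), 2)
  expect_equal(compute_q10(50, 20, 50, 10), 1)
  expect_equal(compute_q10(83.2, 22, 17.2, 10), (83.2 / 17.2)^(10 / 12))
  expect_equal(compute_q10(83.2, 22, 17.2, 10), 3.720, tolerance = 2e-4)
  expect_warning(q <- compute_q10(80, 22, 0, 10), "undefined")
  expect_true(is.na(q))
  expect_error(compute_q10(80, 10, 40, 22), "exceed")

  # composition: Q10 over [T1,T3] is the span-weighted geometric combination
  q13 <- compute_q10(90, 22, 30, 12)
  q12 <- compute_q10(90, 22, 55, 16)
  q23 <- compute_q10(55, 16, 30, 12)
  expect_equal(q13, (q12^(6 / 10) * q23^(4 / 10))^(10 / 10), tolerance = 1e-12)
})

test_that("segment windows partition beats disjointly", {
  p <- ramp_protocol()
  temp <- simulate_temp_trace(p)
  w <- segment_ramp(temp, p)
  b <- make_beat_train(50, duration_s = max(w$end_s), jitter_sd_ms = 30, seed = 9)
  tab <- segment_beats(b, w)
  expect_equal(sum(tab$beat_count), length(b$event_times))
  expect_true(all(tab$start_s[-1] >= tab$end_s[-nrow(tab)] - 1e-9))
})

test_that("cohort Q10 uses the coldest active set-point and skips arrested spat", {
  co <- make_cohort(seed = 6)
  q <- cohort_q10(co)
  expect_true(all(c("cooling", "warming") %in% q$phase))
  expect_true(all(q$t_warm[!is.na(q$q10)] > q$t_cold[!is.na(q$q10)]))
  expect_true(all(q$q10[!is.na(q$q10)] > 0))
  # the fixed 22-vs-10 endpoint variant yields NA for trough-arrested spat
  qt <- cohort_q10(co, endpoints = "trough")
  arrested <- co$segments$spat_id[co$segments$set_point_c == 10 & co$segments$asystole]
  expect_true(all(is.na(qt$q10[qt$phase == "cooling" & qt$spat_id %in% arrested])))
})
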