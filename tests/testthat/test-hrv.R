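ibi_from_values <- function(v_ms, start = 0) {
  onsets <- start + c(0, cumsum(v_ms[-length(v_ms)])) / 1000
  ibi_series(v_ms, onsets)
}

test_that("time-domain HRV matches hand-computed values", {
  const <- ibi_from_values(rep(750, 10))
  h <- time_domain_hrv(const)
  expect_equal(h$mean_ibi, 750)
  expect_equal(h$sdnn, 0)
  expect_equal(h$rmssd, 0)
  expect_equal(h$pnn50, 0)

  alt <- ibi_from_values(c(900, 1000, 900, 1000, 900))
  h2 <- time_domain_hrv(alt)
  expect_equal(h2$mean_ibi, 940)
  expect_equal(h2$rmssd, 100)
  expect_equal(h2$pnn50, 100)
  expect_equal(h2$sdnn, sqrt(12000 / 4))
  expect_equal(h2$sdnn, 54.77, tolerance = 1e-4)

  # pNN50 is strict: a 40 ms and even an exactly-50 ms difference don't count
  expect_equal(time_domain_hrv(ibi_from_values(c(1000, 1040)))$pnn50, 0)
  expect_equal(time_domain_hrv(ibi_from_values(c(1000, 1050)))$pnn50, 0)
  expect_equal(time_domain_hrv(ibi_from_values(c(1000, 1051)))$pnn50, 100)
})

test_that("degenerate IBI inputs yield NA statistics, not errors", {
  empty <- time_domain_hrv(ibi_series(numeric(0), numeric(0)))
  expect_true(all(is.na(c(empty$mean_ibi, empty$sdnn, empty$rmssd, empty$pnn50))))
  one <- time_domain_hrv(ibi_from_values(800))
  expect_equal(one$mean_ibi, 800)
  expect_true(is.na(one$sdnn))
  expect_true(is.na(one$rmssd))
  expect_equal(one$n_pairs, 0)
})

test_that("successive-difference pairs never straddle an exclusion gap", {
  # beats at 0..5 s except a masked gap from 2 to 4 s
  ib <- compute_ibi(beat_series(c(0, 1, 2, 4, 5)), cbind(2.5, 3.5))
  expect_equal(ib$intervals_ms, c(1000, 1000, 1000))
  h <- time_domain_hrv(ib)
  # intervals (0,1) and (1,2) are consecutive; (4,5) is isolated
  expect_equal(h$n_pairs, 1)
})

test_that("a constant shift moves mean IBI only", {
  set.seed(21)
  v <- 800 + rnorm(40, 0, 60)
  h0 <- time_domain_hrv(ibi_from_values(v))
  h1 <- time_domain_hrv(ibi_from_values(v + 250))
  expect_equal(h1$mean_ibi, h0$mean_ibi + 250)
  expect_equal(h1$sdnn, h0$sdnn)
  expect_equal(h1$rmssd, h0$rmssd)
  expect_equal(h1$pnn50, h0$pnn50)
})

test_that("rmssd respects the successive-difference inequality bound", {
  for (s in 1:25) {
    set.seed(400 + s)
    n <- sample(10:200, 1)
    v <- 900 + rnorm(n, 0, 80)
    h <- time_domain_hrv(ibi_from_values(v))
    expect_lte(h$rmssd, 2 * h$sdnn * sqrt(n / (n - 1)) + 1e-9)
  }
})

test_that("the PSD screen recovers an injected LF modulation", {
  f0 <- 0.10
  n <- 400
  onsets <- cumsum(c(0, rep(1, n - 1)))
  v <- 1000 + 50 * sin(2 * pi * f0 * onsets)
  rep_ <- psd_screen(ibi_series(v, onsets))
  expect_true(rep_$evaluable)
  lf <- rep_$peaks[rep_$peaks$band == "LF", ]
  expect_true(lf$peak_found)
  expect_lt(abs(lf$peak_freq - f0), 0.01)
})

test_that("white IBI jitter rarely triggers the peak criterion", {
  hits <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 300
    v <- 1000 + rnorm(n, 0, 40)
    onsets <- cumsum(c(0, v[-n] / 1000))
    rep_ <- psd_screen(ibi_series(v, onsets))
    any(rep_$peaks$peak_found)
  }, logical(1))
  expect_gte(sum(!hits), 18)
})

test_that("constant IBIs and short records produce no peaks / not evaluable", {
  n <- 200
  rep_ <- psd_screen(ibi_series(rep(1000, n), cumsum(c(0, rep(1, n - 1)))))
  expect_true(rep_$evaluable)
  expect_false(any(rep_$peaks$peak_found))

  short <- psd_screen(ibi_series(rep(1000, 10), cumsum(c(0, rep(1, 9)))))
  expect_false(short$evaluable)
})

test_that("the Welch estimator localises a known sinusoid", {
  fs <- 4
  t <- seq(0, 200, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  psd <- spatbeat:::welch_psd(x, fs)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 0.25), 0.02)
  # Parseval: integrated density approximates the signal variance
  expect_equal(sum(psd$power) * diff(psd$freq[1:2]), var(x), tolerance = 0.1)
})

test_that("segment RMSSD falls with temperature in simulated cohorts", {
  co <- make_cohort(seed = 14)
  seg <- co$segments[!co$segments$asystole & !is.na(co$segments$rmssd_ms), ]
  for (g in c("Ta10", "Ta22")) {
    d <- seg[seg$group == g, ]
    sl <- coef(lm(rmssd_ms ~ set_point_c, data = d))[["set_point_c"]]
    expect_lt(sl, 0)
  }
})
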