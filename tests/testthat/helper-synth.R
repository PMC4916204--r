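# Independent single-pass threshold-crossing oracle.
#
# A deliberately plain sample-by-sample state machine, kept separate from
# the package's vectorised detector: an event fires at the first sample
# above `threshold` after the signal has been below `rearm` since the last
# event, honouring the refractory period. Used to cross-check detect_beats
# event counts.
oracle_detect <- function(values, times, threshold, rearm, refractory_s) {
  events <- numeric(0)
  armed <- values[1] < rearm
  last <- -Inf
  for (i in seq_along(values)) {
    v <- values[i]
    if (v > threshold) {
      if (armed) {
        if (times[i] - last >= refractory_s) {
          events <- c(events, times[i])
          last <- times[i]
        }
        armed <- FALSE
      }
    } else if (v < rearm) {
      armed <- TRUE
    }
  }
  events
}

# the detector's own percentile threshold/re-arm pair for a trace
percentile_levels <- function(values, hysteresis_frac = 0.1) {
  q <- quantile(values, c(0.1, 0.9), names = FALSE, type = 7)
  thr <- mean(q)
  c(threshold = thr, rearm = thr - hysteresis_frac * (q[2] - q[1]))
}

# Synthesize a contraction waveform from beat times: an asymmetric
# fast-rise/slow-decay pulse per beat over Gaussian noise, sampled at fs.
# The default noise (2% of pulse amplitude) is about twice the level an
# active-minus-reference trace extracted from the default rendered scene
# carries after disc averaging.
synth_trace <- function(beat_times, duration_s, fs = 60, amp = 1,
                        noise_sd = 0.02, seed = NULL) {
  gen <- function() {
    t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
    v <- numeric(length(t))
    for (tb in beat_times) {
      u <- t - tb
      sel <- u >= 0 & u < 0.4
      x <- u[sel] / 0.06
      v[sel] <- v[sel] + amp * x^2 * exp(2 * (1 - x))
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    contraction_trace(v, fs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# greedy recall/precision of detected events against ground truth
match_events <- function(truth, detected, tol_s = 0.05) {
  if (length(truth) == 0 || length(detected) == 0)
    return(c(recall = NA_real_, precision = NA_real_))
  rec <- mean(vapply(truth, function(t) any(abs(detected - t) <= tol_s), logical(1)))
  pre <- mean(vapply(detected, function(t) any(abs(truth - t) <= tol_s), logical(1)))
  c(recall = rec, precision = pre)
}
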