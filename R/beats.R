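#' Beat series
#'
#' Leading-edge contraction onset times, strictly increasing, in seconds.
#'
#' @param event_times numeric vector of event times (s).
#' @param detector_params optional list recording the detector settings
#'   (threshold, hysteresis fraction, refractory ms) as provenance.
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(event_times, detector_params = NULL) {
  event_times <- as.numeric(event_times)
  if (any(!is.finite(event_times))) stop_param("event times must be finite")
  if (is.unsorted(event_times, strictly = TRUE))
    stop_param("event times must be strictly increasing")
  structure(list(event_times = event_times, detector_params = detector_params),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$event_times)
  cat(sprintf("<beat_series> %d events", n))
  if (n >= 2L)
    cat(sprintf(" over %.1f s (mean rate %.1f beats/min)",
                diff(range(x$event_times)),
                60 * (n - 1) / diff(range(x$event_times))))
  cat("\n")
  invisible(x)
}

#' Read/write beat-event CSV (`event_time_s` header)
#' @param path CSV file path.
#' @return [beat_series()] for `load_beats`; `path` invisibly for `save_beats`.
#' @export
load_beats <- function(path) {
  df <- utils::read.csv(path)
  if (!"event_time_s" %in% names(df))
    stop_param("beats CSV must have column 'event_time_s'")
  beat_series(df$event_time_s)
}

#' @rdname load_beats
#' @param beats a [beat_series()].
#' @export
save_beats <- function(beats, path) {
  utils::write.csv(data.frame(event_time_s = beats$event_times), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect cardiac contractions at the leading edge of a trace
#'
#' An event is timestamped at the first sample where the signal, having
#' previously fallen below the re-arm level `threshold - hysteresis * range`,
#' crosses above the threshold. The default threshold is the midpoint of
#' the 10th and 90th percentiles of the non-excluded samples, which makes
#' detection invariant to overall gain; hysteresis suppresses chatter near
#' the threshold. Events closer than the refractory period to the previous
#' event, or falling inside an exclusion interval, are discarded. Event
#' times are the exact sample times of the crossing samples (no sub-sample
#' interpolation; at 60 fps the 16.7 ms resolution is ample for 50 ms pNN50
#' granularity).
#'
#' @param trace a [contraction_trace()] with at least 2 samples.
#' @param threshold absolute threshold level; `NULL` (default) for the
#'   percentile-adaptive midpoint.
#' @param hysteresis_frac re-arm margin as a fraction of the 10th-90th
#'   percentile range (default 0.1).
#' @param refractory_ms minimum event spacing in ms (default 150, capping
#'   detectable rate at 400 beats/min, far above bivalve maxima); must be
#'   at least 2 sample periods.
#' @param min_range dynamic-range floor: if the 10-90 percentile range of
#'   the trace is below this, the trace is considered flat and an empty
#'   series is returned with a warning (not an error).
#' @return a [beat_series()] carrying the detector settings used.
#' @export
detect_beats <- function(trace, threshold = NULL, hysteresis_frac = 0.1,
                         refractory_ms = 150, min_range = 1e-8) {
  if (!inherits(trace, "contraction_trace")) stop_param("'trace' must be a contraction_trace")
  v <- trace$values
  if (length(v) < 2L) stop_param("trace must have at least 2 samples")
  check_scalar_num(hysteresis_frac, "hysteresis_frac", min = 0)
  check_scalar_num(refractory_ms, "refractory_ms", min = 0)
  if (refractory_ms / 1000 < 2 / trace$sample_rate)
    stop_param("refractory must be at least 2 sample periods")
  t <- trace_times(trace)
  excl <- trace$exclusions
  keep <- !in_exclusion(t, excl)
  if (!any(keep)) keep <- rep(TRUE, length(v))

  q <- stats::quantile(v[keep], c(0.1, 0.9), names = FALSE, type = 7)
  rng <- q[2L] - q[1L]
  if (rng < min_range) {
    warning("no dynamic range in trace; returning empty beat series",
            call. = FALSE)
    return(beat_series(numeric(0),
                       detector_params = list(threshold = NA_real_,
                                              hysteresis_frac = hysteresis_frac,
                                              refractory_ms = refractory_ms)))
  }
  if (is.null(threshold)) threshold <- (q[1L] + q[2L]) / 2
  rearm <- threshold - hysteresis_frac * rng

  # candidate crossings: below re-arm at some earlier point, now above
  # threshold. armed[i] is TRUE once the signal has dipped below the re-arm
  # level at or before sample i since the last event.
  above <- v > threshold
  below_rearm <- v < rearm
  events <- numeric(0)
  armed <- below_rearm[1L]
  last_event <- -Inf
  refr <- refractory_ms / 1000
  # vectorised scan over "state change" samples only
  idx <- which(above | below_rearm)
  for (i in idx) {
    if (above[i]) {
      if (armed && t[i] - last_event >= refr) {
        events <- c(events, t[i])
        last_event <- t[i]
        armed <- FALSE
      } else if (armed) {
        armed <- FALSE  # crossing lost to refractory still de-arms
      }
    } else {
      armed <- TRUE
    }
  }
  if (nrow(excl) && length(events))
    events <- events[!in_exclusion(events, excl)]
  beat_series(events, detector_params = list(threshold = threshold,
                                             hysteresis_frac = hysteresis_frac,
                                             refractory_ms = refractory_ms))
}

#' Inter-beat interval series
#'
#' @param intervals_ms positive intervals, ms.
#' @param onset_times_s time of the earlier beat of each pair, s.
#' @param valid logical validity flag per interval.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(intervals_ms, onset_times_s, valid = rep(TRUE, length(intervals_ms))) {
  if (length(intervals_ms) != length(onset_times_s) ||
      length(intervals_ms) != length(valid))
    stop_param("interval, onset and validity vectors must have equal length")
  if (any(intervals_ms <= 0)) stop_param("intervals must be positive")
  structure(list(intervals_ms = as.numeric(intervals_ms),
                 onset_times_s = as.numeric(onset_times_s),
                 valid = as.logical(valid)),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals (%d valid)",
              length(x$intervals_ms), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf(", mean %.1f ms", mean(x$intervals_ms[x$valid])))
  cat("\n")
  invisible(x)
}

#' Compute validated inter-beat intervals
#'
#' Consecutive beat pairs give intervals in ms. A pair whose spanning time
#' interval intersects any exclusion interval is omitted entirely — a gap
#' is never bridged across an artifact, so no spurious long interval enters
#' the IBI record.
#'
#' @param beats a [beat_series()].
#' @param exclusions optional `start`, `end` matrix/data frame of artifact
#'   intervals (s).
#' @return an [ibi_series()]; empty (not an error) for fewer than 2 beats.
#' @export
compute_ibi <- function(beats, exclusions = NULL) {
  if (!inherits(beats, "beat_series")) stop_param("'beats' must be a beat_series")
  tt <- beats$event_times
  if (length(tt) < 2L)
    return(ibi_series(numeric(0), numeric(0), logical(0)))
  excl <- normalize_exclusions(exclusions)
  a <- tt[-length(tt)]
  b <- tt[-1L]
  drop <- span_intersects(a, b, excl)
  ibi_series((b - a)[!drop] * 1000, a[!drop])
}

#' Mean heart rate from an IBI series
#'
#' `60000 / mean(valid IBIs in ms)`, the rate whose mean interval equals
#' the observed mean interval.
#'
#' @param ibis an [ibi_series()].
#' @return beats/min, or `NA` when no valid interval exists.
#' @export
mean_hr <- function(ibis) {
  v <- ibis$intervals_ms[ibis$valid]
  if (length(v) == 0L) return(NA_real_)
  60000 / mean(v)
}
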