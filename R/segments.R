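#' Classify cardiac asystole from a segment's beat count
#'
#' The working definition of asystole is fewer than 45 contractions within
#' a canonical 10-minute protocol segment; for other window lengths the
#' cutoff scales proportionally, so classification is invariant to cutting
#' a window in half along with its beats.
#'
#' @param beat_count number of detected contractions in the window.
#' @param window_s window length in seconds (> 0).
#' @param beats_per_10min asystole cutoff for a 600 s window (default 45).
#' @return `TRUE` if asystolic (`beat_count < 45 * window_s / 600`).
#' @export
classify_asystole <- function(beat_count, window_s = 600, beats_per_10min = 45) {
  check_scalar_num(window_s, "window_s")
  if (window_s <= 0) stop_param("'window_s' must be > 0")
  if (any(beat_count < 0)) stop_param("'beat_count' must be non-negative")
  beat_count < beats_per_10min * window_s / 600
}

#' Segment a recording along the ramp protocol
#'
#' One segment per protocol step. A segment's usable window begins when the
#' thermocouple reading first settles — stays within +/- 1 deg C of the
#' set-point for the remainder of the step — and ends at the step's
#' scheduled end. Steps whose reading never settles are flagged unusable
#' (window of length 0) but still returned; segments with under 300 s of
#' usable window are flagged low-confidence.
#'
#' @param temp a data frame with columns `time_s`, `celsius` (strictly
#'   increasing times), e.g. from [simulate_temp_trace()] or a thermocouple
#'   CSV.
#' @param protocol a [ramp_protocol()].
#' @param tolerance_c settling tolerance, deg C (default 1, the chamber's
#'   control tolerance).
#' @return a data frame of class `segment_windows`: `step`, `set_point_c`,
#'   `phase`, `start_s`, `end_s`, `usable`, `low_confidence`.
#' @export
segment_ramp <- function(temp, protocol, tolerance_c = 1) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  if (!all(c("time_s", "celsius") %in% names(temp)))
    stop_param("'temp' must have columns 'time_s' and 'celsius'")
  if (is.unsorted(temp$time_s, strictly = TRUE))
    stop_param("temperature times must be strictly increasing")
  s <- protocol$steps
  if (min(temp$time_s) > min(s$start_s) || max(temp$time_s) < max(s$end_s) - 1e-9)
    stop_param("temperature record must span the protocol")
  out <- s[, c("step", "set_point_c", "phase")]
  out$start_s <- NA_real_
  out$end_s <- s$end_s
  out$usable <- TRUE
  for (i in seq_len(nrow(s))) {
    sel <- which(temp$time_s >= s$start_s[i] & temp$time_s < s$end_s[i])
    if (length(sel) == 0L) { out$usable[i] <- FALSE; next }
    ok <- abs(temp$celsius[sel] - s$set_point_c[i]) <= tolerance_c + 1e-9
    # first index from which the reading stays within tolerance to step end
    settled <- which(rev(cumprod(rev(ok))) == 1)
    if (length(settled) == 0L) {
      out$usable[i] <- FALSE
      out$start_s[i] <- s$end_s[i]
    } else {
      out$start_s[i] <- temp$time_s[sel[settled[1L]]]
    }
  }
  out$low_confidence <- !out$usable | (out$end_s - out$start_s) < 300
  class(out) <- c("segment_windows", "data.frame")
  out
}

#' Segment heart rate under an asystole convention
#'
#' @param ibis an [ibi_series()] for the beats inside the segment.
#' @param asystole the segment's asystole flag.
#' @param convention `"active_only"` (undefined, `NA`, when asystolic — the
#'   convention used for HRV and active-spat rate analyses) or `"zeroed"`
#'   (0 when asystolic — the convention under which arrested animals drag
#'   the group mean down).
#' @return beats/min, `NA`, or 0.
#' @export
segment_hr <- function(ibis, asystole, convention = c("active_only", "zeroed")) {
  convention <- match.arg(convention)
  if (asystole) return(if (convention == "zeroed") 0 else NA_real_)
  mean_hr(ibis)
}

#' Q10 temperature coefficient
#'
#' `Q10 = (rate_warm / rate_cold) ^ (10 / (T_warm - T_cold))`: the factor
#' by which the rate changes over 10 deg C.
#'
#' @param hr_warm,hr_cold rates at the warm/cold endpoint (beats/min).
#' @param t_warm,t_cold endpoint temperatures, deg C, `t_warm > t_cold`.
#' @return Q10 (unitless), or `NA` with a warning when an endpoint rate is
#'   zero or missing (arrested animals cannot enter a ratio of rates).
#' @examples
#' compute_q10(80, 22, 40, 12)  # doubling over exactly 10 deg C -> 2
#' @export
compute_q10 <- function(hr_warm, t_warm, hr_cold, t_cold) {
  if (t_warm <= t_cold) stop_param("'t_warm' must exceed 't_cold'")
  if (is.na(hr_warm) || is.na(hr_cold) || hr_warm <= 0 || hr_cold <= 0) {
    warning("Q10 undefined: endpoint rate zero or missing", call. = FALSE)
    return(NA_real_)
  }
  (hr_warm / hr_cold)^(10 / (t_warm - t_cold))
}

#' Per-spat, per-phase Q10 records from a cohort segment table
#'
#' Default endpoints per spat and phase: the phase's warmest set-point and
#' the coldest set-point at which the spat still showed active contraction
#' (asystolic segments cannot enter a ratio of rates). `endpoints =
#' "trough"` instead forces the fixed 22 vs 10 deg C pair, yielding `NA`
#' for spat arrested at the trough.
#'
#' @param segments a cohort segment table (see [make_cohort()]), or a
#'   `cohort_dataset`.
#' @param endpoints `"coldest_active"` (default) or `"trough"`.
#' @return a data frame `spat_id`, `group`, `phase`, `t_warm`, `t_cold`,
#'   `hr_warm`, `hr_cold`, `q10`.
#' @export
cohort_q10 <- function(segments, endpoints = c("coldest_active", "trough")) {
  endpoints <- match.arg(endpoints)
  if (inherits(segments, "cohort_dataset")) segments <- segments$segments
  out <- list()
  for (id in unique(segments$spat_id)) {
    for (ph in unique(segments$phase)) {
      seg <- segments[segments$spat_id == id & segments$phase == ph, ]
      if (nrow(seg) < 2L) next
      act <- seg[!seg$asystole & !is.na(seg$hr_active) & seg$hr_active > 0, ]
      warm <- act[which.max(act$set_point_c), , drop = FALSE]
      cold <- if (endpoints == "coldest_active") {
        act[which.min(act$set_point_c), , drop = FALSE]
      } else {
        seg[seg$set_point_c == min(seg$set_point_c), , drop = FALSE]
      }
      q <- if (nrow(warm) && nrow(cold) && warm$set_point_c > cold$set_point_c) {
        suppressWarnings(compute_q10(warm$hr_active, warm$set_point_c,
                                     cold$hr_active, cold$set_point_c))
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        spat_id = id, group = seg$group[1L], phase = ph,
        t_warm = if (nrow(warm)) warm$set_point_c else NA_real_,
        t_cold = if (nrow(cold)) cold$set_point_c else NA_real_,
        hr_warm = if (nrow(warm)) warm$hr_active else NA_real_,
        hr_cold = if (nrow(cold)) cold$hr_active else NA_real_,
        q10 = q)
    }
  }
  do.call(rbind, out)
}

#' Build a per-segment beat-count table from beats and segment windows
#'
#' Applies the asystole rule and both heart-rate conventions to the beats
#' falling in each usable window. Beats belong to at most one segment
#' (windows are disjoint).
#'
#' @param beats a [beat_series()].
#' @param windows a `segment_windows` table from [segment_ramp()].
#' @param exclusions optional artifact intervals passed to [compute_ibi()].
#' @return the windows table with `beat_count`, `asystole`, `hr_active`,
#'   `hr_zeroed` columns appended.
#' @export
segment_beats <- function(beats, windows, exclusions = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  res <- windows
  res$beat_count <- NA_integer_
  res$asystole <- NA
  res$hr_active <- NA_real_
  res$hr_zeroed <- NA_real_
  for (i in seq_len(nrow(windows))) {
    if (!windows$usable[i]) next
    sel <- beats$event_times >= windows$start_s[i] &
      beats$event_times < windows$end_s[i]
    bt <- beats$event_times[sel]
    win <- windows$end_s[i] - windows$start_s[i]
    asys <- classify_asystole(length(bt), win)
    ib <- compute_ibi(beat_series(bt), exclusions)
    res$beat_count[i] <- length(bt)
    res$asystole[i] <- asys
    res$hr_active[i] <- segment_hr(ib, asys, "active_only")
    res$hr_zeroed[i] <- segment_hr(ib, asys, "zeroed")
  }
  res
}
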