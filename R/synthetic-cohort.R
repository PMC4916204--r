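#' Temperature-ramp protocol
#'
#' The stepped acute-temperature protocol: from a warm start the chamber is
#' cooled in fixed steps to a trough and re-warmed symmetrically, dwelling
#' a fixed time at each experimental temperature. The default is the
#' 22 -> 10 -> 22 deg C ramp in 2 deg C steps with 600 s per step
#' (13 steps); the 10 deg C trough terminates the cooling arm and is
#' labelled `cooling`.
#'
#' @param t_start,t_trough start/trough set-points, deg C.
#' @param step_size step magnitude, deg C (> 0).
#' @param dwell_s dwell time at each set-point, s.
#' @param settle_s nominal settling time of the chamber after a step
#'   change, s (the hardware achieved 2 deg C steps in under 80 s).
#' @return an object of class `ramp_protocol`: a data frame `steps` with
#'   columns `step`, `set_point_c`, `phase`, `start_s`, `end_s`, plus
#'   `step_size` and `settle_s`.
#' @export
ramp_protocol <- function(t_start = 22, t_trough = 10, step_size = 2,
                          dwell_s = 600, settle_s = 0) {
  check_scalar_num(step_size, "step_size")
  if (step_size <= 0) stop_param("'step_size' must be > 0")
  check_scalar_num(dwell_s, "dwell_s")
  if (dwell_s <= 0) stop_param("'dwell_s' must be > 0")
  check_scalar_num(settle_s, "settle_s", min = 0)
  down <- seq(t_start, t_trough, by = -step_size)
  up <- if (t_trough + step_size > t_start) numeric(0)
        else seq(t_trough + step_size, t_start, by = step_size)
  sp <- c(down, up)
  phase <- c(rep("cooling", length(down)), rep("warming", length(up)))
  n <- length(sp)
  steps <- data.frame(step = seq_len(n), set_point_c = sp, phase = phase,
                      start_s = (seq_len(n) - 1) * dwell_s,
                      end_s = seq_len(n) * dwell_s)
  structure(list(steps = steps, step_size = step_size, dwell_s = dwell_s,
                 settle_s = settle_s),
            class = "ramp_protocol")
}

#' @export
print.ramp_protocol <- function(x, ...) {
  s <- x$steps
  cat(sprintf("<ramp_protocol> %d steps, %g s dwell: %s\n", nrow(s),
              x$dwell_s, paste(s$set_point_c, collapse = " ")))
  invisible(x)
}

#' Simulate the thermocouple temperature channel
#'
#' Produces the water-temperature record of a run of the protocol: at each
#' step change the reading relaxes linearly to the new set-point over the
#' protocol's `settle_s`, then holds, with optional Gaussian reading noise.
#'
#' @param protocol a [ramp_protocol()].
#' @param noise_sd reading noise SD, deg C.
#' @param sample_rate samples per second (default 1 Hz).
#' @param seed optional integer seed.
#' @return a data frame of class `temp_trace` with columns `time_s`,
#'   `celsius`.
#' @export
simulate_temp_trace <- function(protocol, noise_sd = 0, sample_rate = 1,
                                seed = NULL) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  s <- protocol$steps
  tt <- seq(0, max(s$end_s), by = 1 / sample_rate)
  temp <- numeric(length(tt))
  prev <- s$set_point_c[1L]
  for (i in seq_len(nrow(s))) {
    sel <- tt >= s$start_s[i] & tt < s$end_s[i]
    u <- tt[sel] - s$start_s[i]
    if (protocol$settle_s > 0 && i > 1L) {
      frac <- pmin(u / protocol$settle_s, 1)
      temp[sel] <- prev + frac * (s$set_point_c[i] - prev)
    } else {
      temp[sel] <- s$set_point_c[i]
    }
    prev <- s$set_point_c[i]
  }
  temp[tt >= max(s$end_s)] <- s$set_point_c[nrow(s)]
  if (noise_sd > 0)
    temp <- temp + with_seed(seed, stats::rnorm(length(temp), 0, noise_sd))
  structure(data.frame(time_s = tt, celsius = temp),
            class = c("temp_trace", "data.frame"))
}

#' Cohort simulation configuration
#'
#' Parameters of the simulated study population: two acclimation groups
#' (cool, `Ta10`, and warm, `Ta22`) of spat whose heart rate declines
#' linearly with acute temperature below 22 deg C, who arrest (asystole)
#' below a spat-specific temperature threshold during cooling and resume
#' at a possibly different threshold during warming, and whose beat-to-beat
#' interval jitter grows as temperature falls.
#'
#' Defaults are the fitted group models of the study this generator
#' emulates: warm-acclimated spat start at 83.2 beats/min at 22 deg C and
#' lose 7.3 beats/min per deg C of cooling (asystole counted as HR 0);
#' cool-acclimated spat start at 78.6 and lose 5.1. Warm-acclimated arrest
#' thresholds centre on 13 deg C (all 8/8 asystolic by 10 deg C);
#' cool-acclimated on 9.5 deg C with SD 1.5 (about 3/8 asystolic at
#' 10 deg C). Resumption occurs 1 deg C colder than arrest, reproducing
#' the observed cooling/warming hysteresis. Jitter SD is 10 ms at
#' 22 deg C, grows 3 ms per deg C of cooling, and is doubled in the
#' cool-acclimated group (whose RMSSD/pNN50 ran higher at every
#' temperature).
#'
#' @param n_per_group spat per acclimation group (default 8).
#' @param groups group labels; first is cool-, second warm-acclimated.
#' @param hr_intercept_22c named per-group HR at 22 deg C, beats/min.
#' @param hr_slope_cooling named per-group HR decline per deg C of cooling,
#'   beats/min (positive = declines when cooled).
#' @param intercept_sd between-spat SD of the 22 deg C intercept, beats/min.
#' @param arrest_threshold_mean,arrest_threshold_sd named per-group arrest
#'   temperature mean/SD, deg C.
#' @param resume_offset resume temperature minus arrest temperature, deg C
#'   (negative: beats resume at a colder temperature than where they
#'   ceased).
#' @param ibi_jitter_sd_at_22c IBI jitter SD at 22 deg C, ms.
#' @param ibi_jitter_growth jitter SD growth per deg C of cooling, ms.
#' @param jitter_group_multiplier multiplier on jitter SD for the
#'   cool-acclimated group.
#' @param residual_beats_max maximum sporadic residual beats emitted in the
#'   first asystolic segment (geometric-decay tail, 1-5).
#' @param seed integer seed for [make_cohort()] when none is passed there.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 8,
                          groups = c("Ta10", "Ta22"),
                          hr_intercept_22c = c(Ta10 = 78.6, Ta22 = 83.2),
                          hr_slope_cooling = c(Ta10 = 5.1, Ta22 = 7.3),
                          intercept_sd = 8,
                          arrest_threshold_mean = c(Ta10 = 9.5, Ta22 = 13),
                          arrest_threshold_sd = c(Ta10 = 1.5, Ta22 = 1.5),
                          resume_offset = -1,
                          ibi_jitter_sd_at_22c = 10,
                          ibi_jitter_growth = 3,
                          jitter_group_multiplier = 2,
                          residual_beats_max = 5,
                          seed = 1L) {
  if (n_per_group < 1) stop_param("'n_per_group' must be >= 1")
  if (length(groups) != 2L) stop_param("exactly two acclimation groups are expected")
  for (nm in c("hr_intercept_22c", "hr_slope_cooling", "arrest_threshold_mean",
               "arrest_threshold_sd")) {
    v <- get(nm)
    if (!all(groups %in% names(v)))
      stop_param(sprintf("'%s' must be named with the group labels", nm))
  }
  if (any(hr_intercept_22c < 0) || any(hr_slope_cooling < 0))
    stop_param("HR intercepts and cooling slopes must be non-negative")
  if (any(arrest_threshold_sd < 0)) stop_param("arrest threshold SDs must be non-negative")
  check_scalar_num(intercept_sd, "intercept_sd", min = 0)
  check_scalar_num(ibi_jitter_sd_at_22c, "ibi_jitter_sd_at_22c", min = 0)
  check_scalar_num(ibi_jitter_growth, "ibi_jitter_growth", min = 0)
  check_scalar_num(jitter_group_multiplier, "jitter_group_multiplier", min = 0)
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 hr_intercept_22c = hr_intercept_22c,
                 hr_slope_cooling = hr_slope_cooling,
                 intercept_sd = intercept_sd,
                 arrest_threshold_mean = arrest_threshold_mean,
                 arrest_threshold_sd = arrest_threshold_sd,
                 resume_offset = resume_offset,
                 ibi_jitter_sd_at_22c = ibi_jitter_sd_at_22c,
                 ibi_jitter_growth = ibi_jitter_growth,
                 jitter_group_multiplier = jitter_group_multiplier,
                 residual_beats_max = as.integer(residual_beats_max),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a ground-truthed cohort
#'
#' For each spat, draws a 22 deg C intercept and an arrest temperature
#' from the group distributions, then generates a beat train for every
#' protocol segment: active segments at rate
#' `max(intercept + slope * (T - 22), 0)` beats/min with
#' temperature-dependent Gaussian IBI jitter; the first asystolic cooling
#' segment carries a short geometric-decay tail of sporadic residual beats
#' (the "increasingly slow, sporadic contractions" seen before full
#' arrest), and later asystolic segments are silent. A spat is asystolic
#' while `T < arrest` during cooling and while `T < arrest + resume_offset`
#' during warming. Segment-level asystole flags, heart rates under both
#' conventions, and time-domain HRV are computed from the generated beats
#' with the package's own analysis operations.
#'
#' @param config a [cohort_config()].
#' @param protocol a [ramp_protocol()].
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   (config, protocol, seed) give identical cohorts.
#' @return an object of class `cohort_dataset`: `spat` (drawn per-spat
#'   parameters — the ground truth), `segments` (one row per spat x
#'   segment: `spat_id`, `group`, `step`, `set_point_c`, `phase`,
#'   `start_s`, `end_s`, `beat_count`, `asystole`, `hr_active`,
#'   `hr_zeroed`, `mean_ibi_ms`, `sdnn_ms`, `rmssd_ms`, `pnn50_pct`),
#'   `beats` (per-spat [beat_series()]), `config`, `protocol`, `seed`.
#' @export
make_cohort <- function(config = cohort_config(), protocol = ramp_protocol(),
                        seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), inherits(protocol, "ramp_protocol"))
  steps <- protocol$steps
  with_seed(seed, {
    ids <- character(0); grp <- character(0)
    for (g in config$groups) {
      ids <- c(ids, sprintf("%s_%02d", g, seq_len(config$n_per_group)))
      grp <- c(grp, rep(g, config$n_per_group))
    }
    n <- length(ids)
    spat <- data.frame(
      spat_id = ids, group = grp,
      intercept = pmax(stats::rnorm(n, config$hr_intercept_22c[grp],
                                    config$intercept_sd), 0),
      slope = unname(config$hr_slope_cooling[grp]),
      arrest_c = stats::rnorm(n, config$arrest_threshold_mean[grp],
                              config$arrest_threshold_sd[grp]))
    spat$resume_c <- spat$arrest_c + config$resume_offset

    seg_rows <- vector("list", n)
    beats_all <- vector("list", n)
    names(beats_all) <- ids
    cool_group <- config$groups[1L]
    for (i in seq_len(n)) {
      mult <- if (grp[i] == cool_group) config$jitter_group_multiplier else 1
      ev <- numeric(0)
      arrested_before <- FALSE
      rows <- vector("list", nrow(steps))
      for (k in seq_len(nrow(steps))) {
        tc <- steps$set_point_c[k]
        thr <- if (steps$phase[k] == "warming") spat$resume_c[i] else spat$arrest_c[i]
        asys_true <- tc < thr
        hr <- max(spat$intercept[i] + spat$slope[i] * (tc - 22), 0)
        jit <- (config$ibi_jitter_sd_at_22c +
                  config$ibi_jitter_growth * max(22 - tc, 0)) * mult
        seg_ev <- numeric(0)
        if (!asys_true && hr > 0) {
          b <- make_beat_train(hr, duration_s = steps$end_s[k] - steps$start_s[k],
                               jitter_sd_ms = jit, t0 = steps$start_s[k])
          seg_ev <- b$event_times
          arrested_before <- FALSE
        } else if (asys_true && !arrested_before && steps$phase[k] != "warming") {
          # residual sporadic tail at arrest onset: a few beats at
          # geometrically widening gaps, then silence
          n_res <- 1L + stats::rbinom(1L, config$residual_beats_max - 1L, 0.4)
          gap <- 60 / max(hr, 5)  # start near the last active interval
          tcur <- steps$start_s[k]
          for (j in seq_len(n_res)) {
            tcur <- tcur + gap * (1 + abs(stats::rnorm(1, 0, 0.2)))
            gap <- gap * 2
            if (tcur < steps$end_s[k]) seg_ev <- c(seg_ev, tcur)
          }
          arrested_before <- TRUE
        } else if (asys_true) {
          arrested_before <- TRUE
        }
        ev <- c(ev, seg_ev)
        rows[[k]] <- data.frame(
          spat_id = ids[i], group = grp[i], step = steps$step[k],
          set_point_c = tc, phase = steps$phase[k],
          start_s = steps$start_s[k], end_s = steps$end_s[k])
      }
      beats_all[[i]] <- beat_series(sort(ev))
      seg_rows[[i]] <- do.call(rbind, rows)
    }
    segments <- do.call(rbind, seg_rows)
    rownames(segments) <- NULL

    # analyse the generated beats segment by segment
    stats_rows <- lapply(seq_len(nrow(segments)), function(r) {
      s <- segments[r, ]
      bt <- beats_all[[s$spat_id]]$event_times
      bt <- bt[bt >= s$start_s & bt <= s$end_s + 1e-9]
      win <- s$end_s - s$start_s
      asys <- classify_asystole(length(bt), win)
      ib <- compute_ibi(beat_series(bt))
      hrv <- time_domain_hrv(ib)
      data.frame(beat_count = length(bt), asystole = asys,
                 hr_active = if (asys) NA_real_ else mean_hr(ib),
                 hr_zeroed = if (asys) 0 else mean_hr(ib),
                 mean_ibi_ms = hrv$mean_ibi, sdnn_ms = hrv$sdnn,
                 rmssd_ms = hrv$rmssd, pnn50_pct = hrv$pnn50)
    })
    segments <- cbind(segments, do.call(rbind, stats_rows))
    structure(list(spat = spat, segments = segments, beats = beats_all,
                   config = config, protocol = protocol, seed = seed),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d spat (%s), %d segments each, seed %d\n",
              nrow(x$spat),
              paste(sprintf("%s n=%d", x$config$groups,
                            table(x$spat$group)[x$config$groups]),
                    collapse = ", "),
              nrow(x$protocol$steps), x$seed))
  asys10 <- x$segments[x$segments$set_point_c == min(x$segments$set_point_c) &
                         x$segments$phase == "cooling", ]
  if (nrow(asys10)) {
    tab <- tapply(asys10$asystole, asys10$group, function(z) sprintf("%d/%d", sum(z), length(z)))
    cat(sprintf("  asystolic at %g deg C: %s\n", min(x$segments$set_point_c),
                paste(names(tab), unlist(tab), sep = " ", collapse = ", ")))
  }
  invisible(x)
}
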