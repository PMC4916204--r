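# evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# normalise an HR profile to a step table (start_s, end_s, hr_bpm)
as_hr_steps <- function(hr_profile, duration_s) {
  if (is.data.frame(hr_profile)) {
    stopifnot(all(c("start_s", "end_s", "hr_bpm") %in% names(hr_profile)))
    steps <- hr_profile[, c("start_s", "end_s", "hr_bpm")]
  } else if (is.function(hr_profile)) {
    if (is.null(duration_s)) stop_param("'duration_s' required for a functional HR profile")
    # piecewise-constant discretisation at 0.5 s resolution
    brk <- seq(0, duration_s, by = 0.5)
    if (brk[length(brk)] < duration_s) brk <- c(brk, duration_s)
    steps <- data.frame(start_s = brk[-length(brk)], end_s = brk[-1L])
    steps$hr_bpm <- hr_profile((steps$start_s + steps$end_s) / 2)
  } else if (is.numeric(hr_profile) && length(hr_profile) == 1L) {
    if (is.null(duration_s)) stop_param("'duration_s' required for a constant HR profile")
    steps <- data.frame(start_s = 0, end_s = duration_s, hr_bpm = hr_profile)
  } else {
    stop_param("'hr_profile' must be a single rate, a function(t), or a step table")
  }
  if (any(steps$hr_bpm < 0)) stop_param("HR profile must be non-negative everywhere")
  if (any(steps$end_s <= steps$start_s)) stop_param("HR steps must have end_s > start_s")
  steps
}

#' Generate a synthetic beat train
#'
#' Beats are laid on a deterministic grid at `60 / HR` second spacing with
#' additive Gaussian jitter on each interval, truncated below at a
#' refractory floor. Interval-based construction makes the inter-beat
#' interval statistics of the train directly controllable, which is what
#' the downstream HRV metrics measure. Where the profile is zero no events
#' are emitted.
#'
#' @param hr_profile heart rate in beats/min: a single non-negative number,
#'   a function of time (s), or a step table with columns
#'   `start_s`, `end_s`, `hr_bpm` (piecewise-constant rate).
#' @param duration_s train duration in seconds (required unless the profile
#'   is a step table, whose span is used).
#' @param jitter_sd_ms standard deviation of the Gaussian interval jitter,
#'   ms (>= 0).
#' @param refractory_ms minimum realisable interval, ms (>= 0); default
#'   150 ms.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param t0 start time offset in seconds.
#' @return a [beat_series()] of strictly increasing event times.
#' @examples
#' b <- make_beat_train(80, duration_s = 60)   # 80 events, all IBIs 750 ms
#' length(b$event_times)
#' @export
make_beat_train <- function(hr_profile, duration_s = NULL, jitter_sd_ms = 0,
                            refractory_ms = 150, seed = NULL, t0 = 0) {
  check_scalar_num(jitter_sd_ms, "jitter_sd_ms", min = 0)
  check_scalar_num(refractory_ms, "refractory_ms", min = 0)
  steps <- as_hr_steps(hr_profile, duration_s)
  with_seed(seed, {
    times <- numeric(0)
    for (i in seq_len(nrow(steps))) {
      hr <- steps$hr_bpm[i]
      if (hr <= 0) next
      base <- 60 / hr
      dur <- steps$end_s[i] - steps$start_s[i]
      n <- ceiling(dur / base) + 2L
      ivl <- pmax(base + stats::rnorm(n, 0, jitter_sd_ms / 1000),
                  refractory_ms / 1000)
      # extend until the grid covers the step (jitter can shorten intervals)
      while (sum(ivl) <= dur) {
        extra <- pmax(base + stats::rnorm(n, 0, jitter_sd_ms / 1000),
                      refractory_ms / 1000)
        ivl <- c(ivl, extra)
      }
      tt <- steps$start_s[i] + cumsum(ivl)
      times <- c(times, tt[tt <= steps$end_s[i] + 1e-9])
    }
    beat_series(t0 + times)
  })
}
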