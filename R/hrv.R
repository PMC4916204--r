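#' Time-domain heart-rate variability
#'
#' The four standard time-domain statistics over the valid ("normal")
#' intervals of a segment:
#' \itemize{
#'   \item `mean_ibi` — arithmetic mean interval, ms;
#'   \item `sdnn` — sample standard deviation (n - 1 denominator), ms;
#'   \item `rmssd` — root mean square of successive differences, ms;
#'   \item `pnn50` — percentage of successive pairs differing by strictly
#'     more than 50 ms.
#' }
#' Successive-difference pairs require consecutive valid intervals: a pair
#' straddling an excluded (invalid) interval or a masking gap never enters
#' `rmssd`/`pnn50`. Consecutiveness is established from the onset times —
#' two intervals are consecutive when the first ends where the second
#' begins.
#'
#' @param ibis an [ibi_series()].
#' @param nn_threshold_ms pNN threshold in ms (default 50).
#' @return an object of class `hrv_summary` with fields `mean_ibi`,
#'   `sdnn`, `rmssd`, `pnn50`, `n_intervals`, `n_pairs`; statistics are
#'   `NA` below their minimum data requirement (2 intervals for `sdnn`,
#'   1 successive pair for `rmssd`/`pnn50`).
#' @examples
#' ib <- ibi_series(c(900, 1000, 900, 1000, 900), cumsum(c(0, 0.9, 1, 0.9, 1)))
#' time_domain_hrv(ib)
#' @export
time_domain_hrv <- function(ibis, nn_threshold_ms = 50) {
  stopifnot(inherits(ibis, "ibi_series"))
  v <- ibis$intervals_ms[ibis$valid]
  on <- ibis$onset_times_s[ibis$valid]
  n <- length(v)
  if (n == 0L)
    return(structure(list(mean_ibi = NA_real_, sdnn = NA_real_,
                          rmssd = NA_real_, pnn50 = NA_real_,
                          n_intervals = 0L, n_pairs = 0L),
                     class = "hrv_summary"))
  # successive pairs: interval k ends at on[k] + v[k]/1000, which must be
  # the onset of interval k+1 (within one ms of slack)
  d <- numeric(0)
  if (n >= 2L) {
    consec <- abs((on[-n] + v[-n] / 1000) - on[-1L]) < 1e-3
    d <- (v[-1L] - v[-n])[consec]
  }
  structure(list(
    mean_ibi = mean(v),
    sdnn = if (n >= 2L) stats::sd(v) else NA_real_,
    rmssd = if (length(d) >= 1L) sqrt(mean(d^2)) else NA_real_,
    pnn50 = if (length(d) >= 1L) 100 * mean(abs(d) > nn_threshold_ms) else NA_real_,
    n_intervals = n, n_pairs = length(d)),
    class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(
    "<hrv_summary> n=%d: mean IBI %.1f ms, SDNN %.2f ms, RMSSD %.2f ms, pNN50 %.1f%%\n",
    x$n_intervals, x$mean_ibi, x$sdnn, x$rmssd, x$pnn50))
  invisible(x)
}

# Welch power spectral density: Hann-windowed overlapping segments,
# one-sided, density normalised so that sum(psd) * df = variance
welch_psd <- function(x, fs, seg_len = 256L, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  u <- sum(win^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    half <- sp[seq_len(nf)]
    # fold negative frequencies into the one-sided density
    if (seg_len %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, power = acc / length(starts))
}

#' Frequency-domain peak screen of an IBI series
#'
#' Resamples the tachogram (IBI against onset time) at 4 Hz by cubic
#' interpolation, estimates its power spectral density with a Welch
#' periodogram (Hann window, 256-sample segments, 50% overlap), and
#' screens the human-analog LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands
#' for a defined peak: a band reports a peak when its maximum is a local
#' maximum of the spectrum exceeding `peak_factor` times the band's median
#' power. Bivalve spectra typically show no such peaks, in which case
#' frequency-domain HRV analysis is not warranted — this screen is the
#' quantitative form of that decision.
#'
#' @param ibis an [ibi_series()] with at least `min_intervals` valid
#'   intervals spanning at least `min_span_s` seconds.
#' @param bands named list of `c(lo, hi)` Hz ranges (non-overlapping).
#' @param resample_hz tachogram resampling rate (default 4 Hz).
#' @param peak_factor peak criterion multiple of band median power
#'   (default 3).
#' @param min_intervals,min_span_s evaluability requirements (64, 120 s).
#' @return an object of class `spectrum_report`: `evaluable`, `freq`,
#'   `power` (ms^2/Hz), and per band `peak_found`/`peak_freq`.
#' @export
psd_screen <- function(ibis, bands = list(LF = c(0.04, 0.15), HF = c(0.15, 0.40)),
                       resample_hz = 4, peak_factor = 3,
                       min_intervals = 64L, min_span_s = 120) {
  stopifnot(inherits(ibis, "ibi_series"))
  b <- do.call(rbind, bands)
  if (any(b[order(b[, 1L]), , drop = FALSE][-1L, 1L] <
          b[order(b[, 1L]), , drop = FALSE][-nrow(b), 2L] - 1e-12))
    stop_param("bands must be non-overlapping")
  v <- ibis$intervals_ms[ibis$valid]
  on <- ibis$onset_times_s[ibis$valid]
  not_eval <- structure(list(evaluable = FALSE, freq = numeric(0),
                             power = numeric(0),
                             peaks = data.frame(band = names(bands),
                                                peak_found = NA,
                                                peak_freq = NA_real_)),
                        class = "spectrum_report")
  if (length(v) < min_intervals || diff(range(on)) < min_span_s)
    return(not_eval)
  grid <- seq(min(on), max(on), by = 1 / resample_hz)
  tach <- stats::spline(on, v, xout = grid, method = "fmm")$y
  psd <- welch_psd(tach, fs = resample_hz)
  peaks <- lapply(names(bands), function(nm) {
    rng <- bands[[nm]]
    sel <- which(psd$freq >= rng[1L] & psd$freq <= rng[2L])
    if (length(sel) < 3L)
      return(data.frame(band = nm, peak_found = NA, peak_freq = NA_real_))
    p <- psd$power[sel]
    imax <- sel[which.max(p)]
    is_local <- imax > 1L && imax < length(psd$power) &&
      psd$power[imax] >= psd$power[imax - 1L] &&
      psd$power[imax] >= psd$power[imax + 1L]
    found <- is_local && max(p) > peak_factor * stats::median(p)
    data.frame(band = nm, peak_found = found,
               peak_freq = if (found) psd$freq[imax] else NA_real_)
  })
  structure(list(evaluable = TRUE, freq = psd$freq, power = psd$power,
                 peaks = do.call(rbind, peaks)),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  if (!x$evaluable) {
    cat("<spectrum_report> not evaluable (insufficient data)\n")
    return(invisible(x))
  }
  cat("<spectrum_report>\n")
  for (i in seq_len(nrow(x$peaks))) {
    p <- x$peaks[i, ]
    cat(sprintf("  %s: %s\n", p$band,
                if (isTRUE(p$peak_found)) sprintf("peak at %.3f Hz", p$peak_freq)
                else "no defined peak"))
  }
  invisible(x)
}
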