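# spatbeat

Non-invasive cardiac monitoring for post-larval oysters (spat) from
trans-illumination video microscopy, and the statistical machinery to
analyse what the heart does under an acute temperature ramp.

Oyster spat (1.1–1.7 mm juveniles) are translucent enough that the beating
heart is visible when lit from below. Pointing a camera at the animal and
comparing pixel colour over the heart against a static reference point
outside the shell yields a contraction waveform without touching the
animal. `spatbeat` implements that pipeline in software and everything
downstream of it:

- **Trace extraction** — an active-disc minus reference-disc intensity
  comparison per frame (directory-of-PNG or multi-page TIFF input),
  invariant to uniform illumination drift.
- **Beat detection** — leading-edge threshold crossing with hysteresis and
  a 150 ms refractory period; the threshold adapts to the 10th–90th
  percentile range of the trace, so detection is gain-invariant.
- **IBI series** — inter-beat intervals (ms) with artifact exclusion:
  a pair spanning an excluded interval (valve motion, waste clearance) is
  dropped, never bridged.
- **Thermal segmentation** — aligns the thermocouple channel with the beat
  record over a stepped ramp (default 22→10→22 °C in 2 °C steps, 10 min per
  step), classifies cardiac **asystole** per segment (fewer than 45
  contractions per 10 min), and computes segment heart rate under two
  conventions (asystolic segments excluded, or counted as HR = 0).
- **HRV** — time-domain metrics per segment: mean IBI, SDNN (sample SD of
  normal intervals), RMSSD = √(mean Δᵢ²) over successive differences Δᵢ,
  and pNN50 (% of |Δᵢ| > 50 ms); plus a Welch-periodogram screen that asks
  whether the IBI spectrum shows any defined LF/HF-band peak at all
  (bivalve spectra typically do not).
- **Q10** — temperature coefficient Q10 = (R_warm/R_cold)^(10/ΔT) per spat
  and ramp phase.
- **Cohort statistics** — exact McNemar and Fisher tests on asystole
  counts; a REML linear mixed model
  HR = β₀ + β_g·group + β_T·(T−22) + β_gT·group·(T−22) + β_ph·phase + uᵢ + ε,
  with a random intercept per spat and AR(1) residuals within spat
  (`nlme`); and two-way ANOVA on ranked Q10.
- **Synthetic data with ground truth** — beat trains, rendered
  beating-heart video, thermocouple channels, and whole two-group cohorts
  (cool- vs warm-acclimated, n = 8 each) with per-spat arrest thresholds
  and temperature-dependent IBI jitter, so the entire pipeline is testable
  end to end without any recording.

## Worked example

From rendered video to HRV:

```r
library(spatbeat)
b  <- make_beat_train(80, duration_s = 30, jitter_sd_ms = 20, seed = 1)
sv <- make_video(b, duration_s = 30, seed = 2)   # 128x128 px RGB @ 60 fps
tr <- extract_trace(sv$frames, sv$roi)
tr
#> <contraction_trace> 1800 samples @ 60 Hz (30.0 s from t0 = 0 s)
#>   range [-0.2032, 0.06192], 0 exclusion interval(s)
beats <- detect_beats(tr)
beats
#> <beat_series> 39 events over 28.6 s (mean rate 79.8 beats/min)
time_domain_hrv(compute_ibi(beats))
#> <hrv_summary> n=38: mean IBI 751.8 ms, SDNN 17.67 ms, RMSSD 25.56 ms, pNN50 5.4%
```

The generator put down 80 beats/min with 20 ms interval jitter; the
detector recovers a 79.8 beats/min series whose mean IBI (751.8 ms) and
RMSSD (25.6 ms ≈ √2·20 ms) match that prescription.

A simulated cohort and the study's mixed model:

```r
co <- make_cohort(seed = 42)
co
#> <cohort_dataset> 16 spat (Ta10 n=8, Ta22 n=8), 13 segments each, seed 42
#>   asystolic at 10 deg C: Ta10 2/8, Ta22 8/8
fit_hr_model(co, convention = "zeroed")
#> Heart rate vs temperature mixed model (zeroed convention, REML, AR(1) residuals)
#>   208 observations, 16 spat
#>                   term estimate    se  lower  upper     p
#>        HR at 22C, Ta10   82.498 2.709 77.189 87.808 0.000
#>        HR at 22C, Ta22   88.089 2.709 82.780 93.399 0.000
#>  cooling decline, Ta10    5.268 0.161  4.953  5.584 0.000
#>  cooling decline, Ta22    7.854 0.161  7.539  8.169 0.000
#>     decline difference    2.586 0.226  2.142  3.029 0.000
#>   intercept difference    5.591 3.768 -1.794 12.977 0.138
#>   random intercept SD 6.90, AR(1) phi 0.159, residual SD 5.55
```

The cohort was generated with a warm-acclimated decline of 7.3 beats/min
per °C (intercept 83.2 at 22 °C) and a cool-acclimated decline of 5.1
(intercept 78.6); the fit recovers both groups' intercepts and declines,
and the warm group's extra steepness under the zeroed convention — the
footprint of its earlier arrest — shows up as a positive decline
difference.

Exact tests on asystole counts take plain integers:

```r
mcnemar_exact(8, 0)                        # 0.0078125
fisher_exact(matrix(c(8, 3, 0, 5), 2))     # 0.02564
```

A thin command-line front end over the same functions lives at
`inst/cli/spatbeat.R` (subcommands `detect`, `segment`, `hrv`, `simulate`,
`stats`).

## Package layout

- `R/synthetic-*.R` — generators (beat trains, video, temperature, cohorts)
- `R/trace.R`, `R/beats.R` — trace extraction and beat/IBI detection
- `R/segments.R`, `R/hrv.R` — ramp segmentation, asystole, Q10, HRV
- `R/stats.R`, `R/model.R` — exact tests, rank ANOVA, the mixed model
- `vignettes/spat-cardiac-monitoring.Rmd` — methods and design notes
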