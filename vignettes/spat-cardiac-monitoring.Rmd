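---
title: "Methods: cardiac contraction detection and HRV in oyster spat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac contraction detection and HRV in oyster spat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatbeat)
```

This vignette records how each stage of the pipeline is defined, which
parameters matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the definition
was genuinely open.

## The measurement model

A trans-illuminated spat is filmed from above; the heart is visible as a
region whose colour changes through the contractile cycle. The software
analog of an analog video edge detector is a scalar **contraction trace**:
per frame, the mean intensity over a small disc on the heart (the *active
point*) minus the mean over a disc on a stationary area outside the shell
(the *reference point*), after projecting colour to a scalar.

Two properties follow directly from this definition and are enforced as
tests: the trace is linear in overall gain, and any spatially uniform,
time-varying illumination component cancels exactly. A disc mean rather
than a single pixel is used because a one-pixel "point" is needlessly
noise-sensitive in a digital image; the disc radius defaults to half the
heart radius in synthetic scenes. The colour projection defaults to
rec.601 luma weights (0.299, 0.587, 0.114) but is configurable because a
real heart's colour change may live mostly in one channel.

## Beat detection

A beat is timestamped at the **leading edge** of each contraction: the
first sample at which the trace, having been below a re-arm level, crosses
above the detection threshold.

* **Threshold** — midpoint of the 10th and 90th percentiles of the
  non-excluded samples. A percentile-adaptive level makes detection
  invariant to gain and robust to a small fraction of artifact samples.
  The behaviour of the original analog comparator is not documented, so an
  absolute override is exposed (`threshold =`).
* **Hysteresis** — the re-arm level sits `hysteresis_frac` (default 0.1)
  of the 10–90 percentile range below the threshold. Without it,
  sample-to-sample noise near the threshold produces chatter; with it, the
  signal must genuinely fall back toward baseline before a new beat can
  fire.
* **Refractory period** — 150 ms (default), capping detectable rate at
  400 beats/min. Spat maxima are near 90 beats/min, so this costs nothing
  and prevents double-firing on pulse overshoot.
* **Timing resolution** — event times are exact sample times; no
  sub-sample interpolation. At 60 frames/s the 16.7 ms resolution is far
  finer than the 50 ms granularity pNN50 cares about.

A trace whose 10–90 percentile range is below `min_range` is treated as
flat: the detector warns ("no dynamic range") and returns an empty series
rather than erroring, because an arrested heart is a legitimate
observation, not a failure.

**Exclusion intervals** are user-supplied `[start, end)` spans (valve
motion, waste excretion, compromised detection). Events inside them are
discarded, and an IBI pair whose span intersects one is omitted entirely —
a gap is never bridged, so artifacts cannot masquerade as long intervals.

## Segmentation, asystole and heart-rate conventions

The acute protocol is a stepped ramp, by default 22 → 10 → 22 °C in 2 °C
steps with 600 s per step (13 steps; the 10 °C trough terminates the
cooling arm and is labelled *cooling*). A segment's usable window starts
when the thermocouple reading first stays within ±1 °C of the set-point
through the step's end — the chamber's own control tolerance — and
segments that never settle are flagged unusable instead of silently
dropped. Windows under 300 s of usable time are flagged low-confidence
but retained.

**Asystole** is a count rule: fewer than 45 contractions in a 10-minute
segment, scaled proportionally for other window lengths (so halving a
window along with its beats cannot flip the classification). Segment
heart rate is `60000 / mean(valid IBI)` and is reported under two
conventions: `active_only` (undefined when asystolic; used for HRV and
active-spat rate analyses) and `zeroed` (0 when asystolic; the convention
under which arrest drags group means down). Sporadic residual beats inside
an asystolic segment never contribute a rate under either convention.

**Q10** is `(R_warm/R_cold)^(10/(T_warm − T_cold))`. The endpoint pair is
genuinely underdetermined for an animal that arrests mid-ramp: a rate of 0
cannot enter the ratio. The default takes, per spat and phase, the phase's
warmest set-point and the coldest set-point at which that spat was still
active; a fixed 22-vs-10 pair is available (`endpoints = "trough"`) and
returns `NA` for trough-arrested spat. Both choices are exposed because
neither is canonical.

## HRV metrics

Time-domain metrics use the valid ("normal") intervals only; no further
ectopy filter is applied because no arrhythmia taxonomy exists for
molluscan hearts. SDNN uses the sample (n−1) standard deviation — the
convention is stated here because software packages differ. pNN50 uses a
strict inequality (|Δ| > 50 ms): a pair differing by exactly 50 ms does
not count. Successive-difference pairs require *consecutive* intervals,
established from onset times (interval k must end where interval k+1
begins, within 1 ms), so RMSSD and pNN50 never straddle a masked gap.

The frequency-domain screen resamples the tachogram at 4 Hz by cubic
interpolation, estimates the PSD with a Welch periodogram (Hann window,
256-sample segments, 50% overlap; the estimator is verified against a
known sinusoid in the test suite, including Parseval consistency), and
declares a band peak only when the band maximum is a local maximum
exceeding 3× the band's median power. The 3× criterion is this package's
operationalisation of a "defined peak" — the underlying biological
observation is qualitative — and is configurable (`peak_factor`). The
LF/HF bands default to the human-analog ranges (0.04–0.15, 0.15–0.40 Hz),
appropriate because spat rates are human-like; both are arguments. A
series needs ≥ 64 valid intervals spanning ≥ 120 s to be evaluable at all.

## The cohort statistics

Asystole contrasts use exact tests: within-group 22 °C-vs-10 °C by the
exact McNemar test (two-sided binomial doubling rule on the discordant
pairs), between-group by Fisher's exact test under the point-probability
rule (every table with point probability ≤ the observed one counts). The
point-probability convention was chosen because it is what mainstream
statistical software computes; the test suite pins `fisher_exact` against
a full hypergeometric enumeration oracle to 1e-12.

Heart rate across the ramp is modelled by REML as

$$HR_{its} = \beta_0 + \beta_g g_i + \beta_T (T_s - 22) +
\beta_{gT} g_i (T_s - 22) + \beta_{ph}\,phase_s + u_i + \varepsilon_{its}$$

with a per-spat random intercept and AR(1) residuals across the ordered
segments within a spat (`nlme::lme` + `corAR1`). Temperature is centred
at 22 °C so each group's intercept is its rate at the ramp start; phase is
coded cooling = 0, warming = 1, with the initial 22 °C step belonging to
cooling. The coefficient on (T − 22) is positive when the heart slows
under cooling and is reported directly as the *cooling decline* in
beats/min per °C. Confidence intervals are Wald-type on the REML fit;
denominator-degrees-of-freedom corrections are deliberately out of scope,
so small-sample p-values are approximate. If the AR(1) fit fails to
converge the model is refit with independent residuals, loudly flagged
(`converged = FALSE`). Under the `zeroed` convention asystolic segments
enter as ordinary observations of 0 — how a rate of exactly zero should
interact with an AR(1) residual process is not well defined in any
convention, and treating it as data is the transparent choice.

Q10 inference uses a two-way ANOVA (group × phase) on globally
rank-transformed values, mid-ranks for ties. When every value is tied
there is no variation to partition and all F are reported as 0 with p = 1;
an empty cell drops the interaction with a warning. All tests are
two-sided with no multiplicity correction, matching the analysis design
this package mirrors.

## What the synthetic generator emulates

The generator produces ground-truthed data at three levels.

**Beat trains** are deterministic grids at 60/HR s spacing with additive
Gaussian jitter per interval, truncated at the 150 ms refractory floor.
An interval-based construction (rather than an inhomogeneous point
process) was chosen because every downstream statistic is interval-based,
which makes the generating IBI mean and SD directly controllable. No
distributional form for bivalve IBI jitter is established; Gaussian on
intervals is a modelling choice, flagged as such.

**Video** renders a shell ellipse on a bright background with a heart
disc that brightens by a gamma-shaped pulse (peak at 60 ms, decayed by
~300 ms — an asymmetric leading edge like a real contraction) at each
ground-truth beat time, over per-pixel Gaussian noise. Default scene:
128 × 128 px RGB at 60 fps, pulse amplitude 0.25, noise SD 0.02 on the
[0, 1] scale. After disc averaging, the extracted trace carries noise
near 1% of pulse amplitude; the suite's trace-level fixtures use 2% to
stay on the conservative side of that operating point.

**Cohorts** combine the two: per spat, a 22 °C intercept drawn from its
acclimation group's distribution (between-spat SD 8 beats/min), the
group's linear cooling decline, an arrest temperature drawn per spat, and
IBI jitter whose SD grows linearly with cooling. The defaults are the
conditions of the study the package emulates:

| parameter | Ta10 (cool) | Ta22 (warm) | why |
|---|---|---|---|
| HR at 22 °C (beats/min) | 78.6 | 83.2 | the groups' fitted intercepts |
| cooling decline (beats/min/°C, zeroed) | 5.1 | 7.3 | the groups' fitted slopes |
| arrest threshold mean (°C) | 9.5 | 13 | reproduces 3/8 vs 8/8 asystolic at 10 °C with SD 1.5 |
| resume offset (°C) | −1 | −1 | beats resume at a colder step than where they ceased |
| IBI jitter at 22 °C (ms) | 20 | 10 | cool group carries higher RMSSD/pNN50 throughout |
| jitter growth (ms/°C of cooling) | ×2 of 3 | 3 | HRV rises as temperature falls |

The spat that crosses its arrest threshold emits a short geometric-decay
tail of 1–5 sporadic beats — increasingly slow contractions before full
arrest — then silence; later cold segments are silent from the start, so
asystole is monotone in temperature during cooling.

**What passing tests do and do not show.** The generator reproduces the
*structure* of real recordings: pulse-like waveforms, rate–temperature
coupling, arrest with hysteresis, jitter growth, artifact masking. It does
not emulate photorealistic anatomy, valve-motion transients beyond
user-injected exclusion intervals, heart drift within the frame (ROI
tracking is an explicit non-goal — the experimenter positions the active
point), non-Gaussian jitter, or arrest as a gradual rate collapse rather
than a threshold. Consequently the end-to-end detection guarantees
(≥ 98% recall/precision) are statements about this noise model, not about
arbitrary field recordings. Note also that a linear HR(T) generator
implies a Q10 that varies with the endpoint pair and differs between
groups with different slopes; empirical Q10 magnitudes from live animals
are therefore not a quantity this generator tries to match, and only the
inference machinery around Q10 is validated.

## Numerical choices and degenerate inputs

* Exclusion intervals are normalised (sorted, overlaps merged) on entry;
  all interval logic is half-open `[start, end)`.
* The detector de-arms on a crossing suppressed by the refractory period,
  so one physical upstroke can never fire twice.
* Near-integer sample rates recovered from CSV time stamps are snapped to
  the integer when within 1e-6 relative, undoing decimal truncation in
  written files.
* `compute_ibi` with fewer than two beats, and `time_domain_hrv` with an
  empty series, return empty/NA results rather than errors; a flat trace
  warns and returns no beats.
* The mixed model optimises with `opt = "optim"`, which also handles the
  zero-residual-variance limit of noise-free simulations (recovered
  exactly, to 1e-6, in the suite).

## Problem sizes

The test suite and the acceptance script size their simulations as
follows: 1,000 synthetic traces (990 waveform-level at 30 s, 10 fully
rendered videos at 8 s) for the detector-oracle comparison; 20 replicate
cohorts (16 spat × 13 segments) for mixed-model parameter recovery, with
50 replicates for the bias check in the model's linear regime; 2,000
null tables for the Fisher type-I check; 20 seeds for the PSD
false-positive rate. These sizes give Monte-Carlo error comfortably below
the tolerances being asserted while keeping a full run in the low
minutes.
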