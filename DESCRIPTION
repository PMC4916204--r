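Package: spatbeat
Title: Cardiac Contraction Detection and Heart-Rate Variability Analysis
    for Oyster Spat Under Thermal Ramps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive cardiac monitoring of post-larval oysters (spat)
    from trans-illumination video microscopy. Extracts a contraction
    waveform from an active-versus-reference pixel region comparison,
    detects beats at the leading edge of each contraction, derives
    validated inter-beat intervals with artifact exclusion, segments
    recordings along a stepped temperature-ramp protocol, classifies
    cardiac asystole per segment, and computes time-domain heart-rate
    variability (mean IBI, SDNN, RMSSD, pNN50), a frequency-domain peak
    screen, Q10 temperature coefficients, and cohort-level inference
    (exact McNemar and Fisher tests, a linear mixed model of heart rate
    on temperature with AR(1) within-animal residuals, and rank-based
    two-way ANOVA). Includes a ground-truthed synthetic-data generator
    producing beat trains, contraction waveforms, rendered video frames,
    and whole simulated cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
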