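Package: predyad
Title: Caregiver Sensory Predictability and Infant Attention Psychophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and inference chain for studies linking the
    predictability of caregiver sensory signals to infant attention and
    autonomic function. Converts micro-coded caregiver auditory/visual/tactile
    event logs into composite-state transition sequences and scores their
    Shannon entropy rate; computes baseline heart-rate variability (RMSSD),
    mean heart rate and cohort-level winsorization from inter-beat-interval
    data; implements heart-rate-defined sustained-attention segmentation with
    deceleration scoring; derives relative frontal theta power from
    Hanning-windowed FFTs of 1-second EEG segments with amplitude-based
    segment rejection; and fits full-information maximum-likelihood (FIML)
    regressions under missing data with robust-SE, multiple-imputation and
    listwise sensitivity checks, Little's MCAR test, covariate screening and
    sensitivity (minimal-detectable-effect) power analysis. A synthetic dyad
    generator produces all inputs with controllable entropy rate, RMSSD,
    planted heart-rate decelerations, condition-modulated theta power and
    planted standardized effects, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
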