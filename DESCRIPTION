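Package: physioload
Title: Physiological Correlates of Cognitive Load from fNIRS and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of cardiac and ocular markers of cognitive load from
    raw physiological signals, and prediction of subjective and behavioural
    workload measures. Instantaneous heart rate and a spectral heart-rate
    variability index (the high-frequency share of heart-rate power) are
    recovered from the cardiac pulsation carried by continuous-wave fNIRS
    optical signals; blink events and blink rate are recovered from
    multi-channel EEG via independent component analysis. Per-episode
    features feed Pearson correlation, multivariate regression (adjusted R)
    and a cascade-forward neural network trained by Levenberg-Marquardt and
    scored by repeated five-fold cross-validated correlation. A synthetic
    multi-subject session generator with full ground truth (respiratory
    sinus arrhythmia, Mayer waves, blink transients, dual-task behaviour)
    makes every stage verifiable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    ica,
    e1071,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
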