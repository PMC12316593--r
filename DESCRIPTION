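Package: bpwave
Title: Beat-to-Beat Arterial Blood Pressure Estimation from ECG and Pulse
    Oximetry Waveforms
Version: 0.1.0
Authors@R:
    person("bpwave", "maintainers", email = "bpwave@example.org",
           role = c("aut", "cre"))
Description: Non-invasive, beat-to-beat estimation of systolic and diastolic
    arterial blood pressure from multichannel ECG and SpO2 (plethysmographic)
    waveforms, with intra-arterial ABP as the gold standard. Provides a
    physiologically structured waveform simulator with exact ground truth;
    signal-quality screening of 4-second windows (hard artifact screens, six
    quality indices, and a small hybrid convolutional classifier); baseline
    wander and pacing-spike suppression; wavelet ECG delineation and slope-sum
    pulse valley detection; assembly of contiguous beat sequences with median
    gold-standard pressures; a 48-entry morphological and demographic feature
    vector; random-forest regression (general, subject-specific, and augmented
    subject-specific, with out-of-bag permutation importance); and
    device-standard evaluation (MAE, Bland-Altman limits, BHS grades, AAMI
    criterion, windowed cross-correlation tracking lag).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
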