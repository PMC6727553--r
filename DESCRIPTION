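Package: somnotree
Title: Rule-Based Five-Stage Sleep Scoring for Rat EEG and EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automatic vigilance-state classification for rat polysomnography.
    Segments one EEG channel and one EMG channel into 10-second epochs of five
    2-second segments, extracts ten spectral and temporal features (band powers
    in dB, band power ratios, and rectified EMG energy), normalizes them per
    recording by extreme-decile scaling, derives stage indexes, and classifies
    every epoch into wake, NREM1, NREM2, transition sleep, or REM via a
    two-part hierarchical decision tree with seven testing points, including
    movement-artifact detection and a collapse to the classical 3-stage
    (wake/NREM/REM) scheme. Also provides confusion-matrix agreement statistics
    (sensitivity, specificity, predictive values, overall agreement, Cohen's
    kappa with Landis-Koch interpretation), expert-consensus filtering, EDF and
    delimited-text signal I/O, and a seedable synthetic polysomnography
    generator with known ground-truth hypnograms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
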