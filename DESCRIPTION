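Package: semgrip
Title: Surface-EMG Grip Detection, Adaptive Serious-Game Simulation and
    Muscle-Fatigue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A testable re-implementation of a wearable surface-electromyography
    (sEMG) grip-rehabilitation stack: a synthetic 500 Hz sEMG simulator with
    known grip-event ground truth and controllable median-frequency drift
    (fatigue); the wearable's four-state calibration sequence, rolling-amplitude
    trigger detection and 60-percent threshold rule; a headless adaptive
    obstacle-jumping game with success-rate driven difficulty; the offline
    bandpass/normalize/rectify/peak-picking pipeline with median-frequency (MDF)
    and mean-peak-amplitude (MPA) fatigue metrics; and a tolerance-based event
    matching layer with F1 scoring, two-sample comparisons and questionnaire
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
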