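Package: stopdyn
Title: Stop-Signal Task Dynamics: EMG Burst Timing, SSRT Estimation, and
    Corticospinal Suppression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level analysis of stop-signal task recordings: EMG
    preprocessing (TMS artifact interpolation, zero-phase Butterworth
    filtering, RMS envelopes) and burst onset/peak/offset detection with
    backtracking thresholds; race-model (integration) and kinematic
    (peak-velocity) estimators of the stop-signal reaction time;
    motor-evoked-potential amplitude extraction with pre-stimulus gating and
    baseline-normalized suppression time courses; and the accompanying
    inferential layer (paired contrasts with effect sizes, robust bisquare
    regression, two-way repeated-measures ANOVA, per-trial precedence
    proportions). Includes a synthetic-data generator built on an independent
    horse-race model with an adaptive stop-signal-delay staircase and a
    forward model for EMG, cursor kinematics and MEP signals, so every
    estimator can be validated by parameter recovery against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
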