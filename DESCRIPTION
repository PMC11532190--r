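Package: cufflessbp
Title: Cuffless Blood-Pressure Tracking Evaluation with ISO 81060-3-Style Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating continuous cuffless blood-pressure estimates
    against a beat-to-beat reference under a three-activity laboratory stressor
    protocol (isometric handgrip, mental arithmetic stress, cold pressor).
    Provides a synthetic protocol-cohort generator (beat-to-beat pressure
    trajectories, parametric pulse waveforms, brachial cuff triplets, PPG-style
    feature streams and a configurable device error model), waveform-to-beat
    processing with artifact masking and 15-second segment aggregation,
    per-activity brachial recalibration of the reference plus one-time offset
    calibration of the device, a subject-wise 3-fold cross-validated ridge
    regression ensemble for systolic, diastolic and mean arterial pressure, and
    the ISO 81060-3-style Accuracy, Stability and Change statistics with
    Bland-Altman agreement, intraclass correlation and a pass/fail criteria
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
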