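Package: wristfall
Title: Threshold-Based Smartwatch Fall Detection, Simulation and
    Diagnostic-Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects falls and near falls in wrist-worn tri-axial
    accelerometer traces with a three-phase threshold state machine
    (free-fall dip, impact spike, post-impact rest), including per-subject
    threshold calibration and a 20% "close to threshold" near-fall margin.
    Ships a seeded simulator of induced-fall study sessions (directed
    forward/backward/left/right falls, step-recovery near falls, free
    walking) with ground-truth event logs, blinded event matching against a
    reference log, and the full diagnostic-accuracy battery: sensitivity,
    specificity, predictive values, likelihood ratios and accuracy with
    exact Clopper-Pearson, prevalence-based logit and log-method confidence
    intervals, plus stratified chi-square comparisons. A command-line
    interface wires simulate, detect, calibrate, evaluate and report steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
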