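Package: srpvep
Title: Stimulus-Response Potentiation and Adaptation Analysis of Chronic
    Visual Evoked Potential Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chronic local-field-potential recordings of
    visual evoked potentials (VEPs) in head-fixed mice. Extracts per-reversal
    and averaged VEP waveform metrics, quantifies long-term stimulus-response
    potentiation across days and short-term within-block adaptation with
    fixed-time-constant exponential fits, conditions responses on behavioural
    state from wheel and pupil data, computes an elastic-net
    regularisation-path regressor-impact metric, and provides group-level
    statistics and a tau-burden grey-level quantification. Includes a
    synthetic session generator with known ground truth so every stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
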