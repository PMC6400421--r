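Package: serialdep
Title: Serial Dependence in Perceptual Decisions: Analysis and
    Population-Coding Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and modeling serial dependence in
    psychophysical adjustment and forced-choice tasks. Provides multilevel
    derivative-of-Gaussian (DoG) fitting of trial-wise errors with a
    subject-level random amplitude, bias residualization for orientation
    and size tasks, reaction-time and Grubbs outlier filtering,
    permutation and cross-validation comparison of previous-stimulus
    versus previous-response predictor models, dominance analysis,
    signal-detection (d-prime) analyses, and two data-generating
    population-coding simulators (a Gain model and a Two-process model of
    adaptation plus decisional-template reweighting) together with the
    three-step calibration procedure used to fit them. A synthetic-data
    module generates trial designs and behavior with known ground truth so
    the whole pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
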