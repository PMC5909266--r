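Package: respmotion
Title: Surrogate-Based Estimation of Respiratory Target Motion for Radiotherapy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the three-dimensional position of a moving thoracic or
    abdominal radiotherapy target from external infrared abdominal markers.
    Implements a quadratic position-plus-velocity regression trained over short
    modeling periods, a piecewise-linear eight-phase comparator model, and a
    median-based baseline-drift correction applied between temporally separate
    scans. Includes an intra-/inter-scan validation framework with RMSE grid
    sweeps over modeling and correction periods, respiratory-pattern
    descriptors (period, amplitude, surrogate-target correlation), and a
    quasi-periodic breathing simulator with drift, noise and
    irregular-breathing events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
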