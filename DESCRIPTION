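Package: sparsecop
Title: Sparse-Sensor Center-of-Pressure Estimation with an Anatomical
    Foot Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the center of pressure (CoP) under each foot and
    the total center of pressure (CoPT) of the body from a small number
    of discrete plantar pressure sensors.  An anatomical foot model (a
    rigid internal shape covered by an elastic medium whose compression
    generates pressure through a logarithmic law) serves as a forward
    simulator of quiet-standing pressure-map recordings; total force and
    ankle moments are learned as linear forms of sub-matrix sensor
    signals by ordinary least squares; per-foot CoP and two-foot CoPT
    follow from the fitted moments.  Includes a robustness-evaluation
    harness sweeping sensor number, size and position with RMS and SD
    error reporting, plus a plain-text recording container and
    configuration formats for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
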