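Package: pcruq
Title: Sample-Specific Prediction Uncertainty for Principal Component
    Regression Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Principal component regression (PCR) calibration of spectra with
    a per-sample decomposition of the expected squared prediction error into
    random error, estimation variance, and omitted-component bias. Includes
    Savitzky-Golay derivative preprocessing, leave-one-out cross-validation
    curves (MSEC/MSECV/MSEP), significance-gated bias estimation, a
    least-squares-effect shrinkage line, Loess tendency diagnostics, a
    synthetic near-infrared spectra simulator with known ground truth, a
    Monte-Carlo oracle for the error formula, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
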