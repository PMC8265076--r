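Package: robits
Title: Robust Interrupted Time Series Models with an Estimated Change-Point
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmented-regression models for single- and multi-unit
    interrupted time series in which the change-point is estimated from the
    data rather than fixed at the intervention date.  The mean function is
    piecewise linear with unit-specific level and trend changes, errors
    follow a phase-specific AR(1), exchangeable, or independent correlation
    structure, and all parameters are estimated jointly by iteratively
    re-weighted least squares (generalized least squares for the mean,
    method of moments for the noise) with the global change-point chosen by
    conditional-likelihood profiling over a user-specified candidate set.
    Includes a supremum Wald test for the existence of a change-point with
    Benjamini-Hochberg multiplicity correction, a synthetic-data generator
    matching the model's stochastic structure, CSV/TSV ingestion with
    linear interpolation of interior missing values, tabular report
    generation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
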