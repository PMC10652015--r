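Package: synchrofluor
Title: Derivative Synchronous Spectrofluorometry for Overlapping Fluorophore Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for resolving and quantifying pairs of strongly overlapping
    fluorophores (harmaline/harmine-like beta-carboline alkaloids, with and
    without cyclodextrin complexation) by derivative synchronous
    spectrofluorometry. Simulates excitation-emission matrices, extracts
    synchronous spectra at a fixed wavelength offset, applies a 9-point
    Savitzky-Golay first derivative, selects interference-free analytical
    wavelengths by the zero-crossing technique, fits linear calibrations with
    ICH Q2 detection and quantification limits, and runs full assay-validation
    studies (accuracy, precision, robustness, specificity, offset screening)
    on seeded synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
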