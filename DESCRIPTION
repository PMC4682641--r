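Package: frapkin
Title: Photobleaching Kinetics of Heterochromatin Proteins: Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies fluorescence recovery after photobleaching (FRAP) and
    fluorescence loss in photobleaching (FLIP) experiments on nuclear proteins
    that exchange between a free pool, chromatin-bound foci, and an RNA-bound
    state. Provides trace extraction from multi-page TIFF time series,
    background subtraction and plateau normalization, one- and two-component
    exponential recovery fits with nested-model selection, half-recovery times,
    whole-nucleus-corrected mobile fractions, high-speed line-scan FRAP
    analysis, and cohort statistics across conditions and cell-cycle phases.
    A three-state stochastic exchange simulator with a matrix-exponential
    mean-field oracle generates synthetic image stacks and line scans with the
    statistical structure the analysis assumes, so every stage is testable
    without microscope data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
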