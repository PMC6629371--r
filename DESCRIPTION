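Package: spinedyn
Title: Longitudinal Dendritic Spine Dynamics and Astrocyte Sholl Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of chronically imaged dendritic protrusions tracked
    across two-photon imaging sessions: two-session turnover ratios,
    filopodial and morphology-class fractions, spine density, per-mouse
    survival curves with single-phase exponential decay fits
    (permanent/impermanent spine fractions and characteristic lifespan),
    stable/recurrent/transient spine classification, and nested-model
    comparison of decay fits by the extra sum-of-squares F test. Includes a
    synthetic spine-kinetics simulator with known ground truth for
    parameter-recovery and calibration studies, and SWC-based Sholl
    morphometry of astrocyte arbors (shell intersections, primary branches,
    longest-tree and total process length).
License: MIT
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
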