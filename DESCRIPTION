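Package: immunoscape
Title: Spatial Immune Profiling of Tumor Serial Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tumor immune microenvironment from serial-section
    immunohistochemistry cell-detection tables. Registers marker slides to a
    reference slide (rigid plus demons non-rigid registration on downsampled
    density rasters, with point transfer through the upsampled deformation
    field), derives tumor-core and invasive-margin regions from pathologist
    annotations, computes per-region positive-cell densities, tile-based
    hotspot densities, Morisita-Horn colocalization indices and the
    percentile-based Immunoscore, and runs the cohort-level prognostic
    statistics (group t-tests, ROC-derived cutoffs, Kaplan-Meier/log-rank,
    multivariate Cox). Ships a synthetic-cohort generator (Thomas cluster
    point patterns, planted misalignments, proportional-hazards survival) so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    survival,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
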