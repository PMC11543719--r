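Package: mosscreen
Title: Moss-Biomonitor Screening of Trace-Element Deposition Around a Point Source
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening trace-element deposition gradients around a
    point source (such as a solid-waste incinerator) using moss or lichen
    biomonitors. Implements detection-limit processing of ICP-MS element
    panels (half-MDL substitution, censoring-based exclusion), local-linear
    Gaussian-kernel nonparametric regression of log10 concentration on log10
    distance with leave-one-out cross-validated R-squared (xR2) smoothing
    selection, aluminum- and cerium-based geogenic residual corrections, a
    near/far exceedance screening report against reference percentiles, and a
    synthetic transect generator for testing and parameter-recovery
    experiments without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
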