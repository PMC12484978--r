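Package: neurostates
Title: Neural State Segmentation and Age-Effect Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven segmentation of naturalistic fMRI time series into
    neural states via Greedy State Boundary Search (GSBS) with t-distance
    model selection, together with the surrounding analysis pipeline:
    searchlight construction over voxel grids, Procrustes hyperalignment of
    subjects within age groups, state-duration and boundary-strength metrics,
    a chance-corrected absolute-overlap statistic between neural state
    boundaries and perceived event boundaries, rank-based age-group inference
    with false-discovery-rate control, and noise/boundary-shift validation
    simulations. Includes a synthetic-cohort generator with planted ground
    truth so every stage is testable without access to restricted imaging
    data.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
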