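Package: spacerdose
Title: Proton Dose Consequences of Iodinated Rectal Hydrogel Spacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how the material assignment of an iodinated rectal
    hydrogel spacer changes proton therapy dose. Provides synthetic pelvic
    CT phantoms with contoured regions of interest, elemental-composition
    stopping-power-ratio (SPR) physics with HU-to-SPR calibration and
    scenario overrides (CT-intensity-based, water, true material), a
    deterministic pencil-beam spread-out-Bragg-peak dose engine for
    two-lateral-beam prostate plans, 3D gamma-index comparison with
    structure-specific passing ratios, DVH/EUD dosimetric indices with
    institutional constraint reports, and paired sign-flip permutation
    tests over a simulated patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
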