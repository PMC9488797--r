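Package: gnotocal
Title: Isolator-Housed Indirect Calorimetry Analysis for Gnotobiotic Mouse Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-animal indirect calorimetry of
    germ-free, gnotobiotic and conventionally colonized mice housed in
    isolator-based metabolic cages. Provides datapoint quality control for
    24-minute cage recordings, gas-exchange computation (Haldane
    transformation, Weir energy expenditure, hydrogen production),
    circadian phase summaries (trapezoid area under the curve, cumulative
    food intake, penalized-spline smoothing), regression-based (ANCOVA)
    covariate normalization of energy expenditure and hydrogen production,
    energy-balance accounting with first-order propagation of measurement
    uncertainty, bead-normalized flow-cytometry bacterial densities, and a
    synthetic-cohort generator so the full pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
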