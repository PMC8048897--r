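Package: barkfissure
Title: Bark Fissure Index and Bark Carbon from Bark-Gauge Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the true (air-space-corrected) volume and
    carbon content of tree bark from non-destructive bark-gauge measurements.
    Implements the bark fissure index (BFI), the relative bark thickness and
    relative bark area allometric relations, bark-carbon conversion equations
    based on basal area, stem volume, biomass or tree carbon, t-quantile based
    sampling-error planning for the number of gauge readings per tree, the
    reference contour and digitized cross-section (polygon) methods, and a
    seeded synthetic cross-section simulator with analytically known truth for
    Monte Carlo validation of the gauge estimator.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
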