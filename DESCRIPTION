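Package: grscreen
Title: Growth-Rate-Corrected Drug Screening Analytics for Patient-Derived
    Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for three-dimensional organoid viability
    screens. Normalizes plate-reader luminescence to day-0 seeding controls,
    computes growth-rate-corrected (GR) and relative-viability dose-response
    values, fits sigmoidal curves, and derives per model-drug metrics (GR50,
    GEC50, GR_inf, GR_aoc, cytostatic dose, EC50, IC50, GI50). Provides
    cross-screen statistics (model and drug ranking, hierarchical clustering,
    Mann-Whitney group comparisons with Hodges-Lehmann shifts, GR50-GI50
    concordance, replicate reproducibility, clinical benefit ratios), Loewe
    additivity synergy scoring for two-drug dose matrices, in vivo tumor
    growth and recurrence statistics, and seeded synthetic-data generators
    that emulate the full screen design with known ground truth.
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
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
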