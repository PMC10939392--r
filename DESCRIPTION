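Package: n2obudget
Title: Full-Scale Nitrous Oxide Emission Inventory and Natural Soil Flux Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a full-scale (anthropogenic plus natural) nitrous oxide
    emission inventory at annual, province-level resolution. Anthropogenic
    sources in four sectors (agriculture, energy, industry, waste) are
    computed with emission-factor accounting in the style of the IPCC 2019
    refinement, including climate-region-stratified soil emission factors,
    manure nitrogen flows, plant-level industrial abatement, and a
    protein-based wastewater nitrogen load. Natural forest and grassland
    emissions come from a reduced-form annual soil nitrogen-cycle model with
    four microbial N2O pathways (autotrophic and heterotrophic nitrification,
    nitrifier and denitrifier denitrification), gridded simulation, and
    factorial driver attribution for CO2, nitrogen deposition and climate.
    Uncertainty is propagated by Monte Carlo over activity data and emission
    factors and by Markov chain Monte Carlo calibration of the soil model.
    Reporting utilities cover aggregation, sector shares, decadal changes,
    linear trends, Mann-Kendall tests and inventory export, together with a
    synthetic activity-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    tidyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
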