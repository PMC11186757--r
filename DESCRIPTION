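Package: pbudget
Title: Ecosystem Phosphorus Budgets and CO2 Effect Sizes for Small-n FACE Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles whole-ecosystem phosphorus (P) budgets from long-format
    plot-level field measurements: plant P pools by the concentration-by-biomass
    approach, soil P pools from depth-resolved concentrations and bulk density,
    microbial biomass P from chloroform-fumigation extract pairs, Hedley
    fractionation grouping, annualized litterfall and in-situ net-mineralization
    fluxes, and derived indicators (mean residence time, P-use efficiencies).
    Computes CO2 treatment effect sizes for two-treatment, three-plot Free-Air
    CO2 Enrichment (FACE) designs using pooled standard deviations, t-based
    confidence intervals at three confidence levels, and bootstrap resampling,
    together with coverage-simulation harnesses. A configurable synthetic-data
    generator emulates the sampling design of a mature-forest FACE experiment so
    the full pipeline is testable without access to deposited field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
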