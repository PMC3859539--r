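Package: ssbimpact
Title: Projected Health and Cost Impact of Reduced Sugar-Sweetened Beverage
    Consumption
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects the ten-year health and medical-cost impact of reduced
    sugar-sweetened beverage (SSB) consumption in an adult population modelled
    on California. Translates an excise tax into a consumption change via
    price elasticity, cascades that change through body-mass index, systolic
    blood pressure, lipids and diabetes risk, runs an annual-cycle
    state-transition simulation of diabetes and coronary heart disease with
    baseline-hazard calibration to anticipated case counts, and converts
    averted cases into CPI-adjusted, discounted direct medical-cost savings.
    Includes a seeded synthetic-population generator, scenario and
    sensitivity grids, and subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
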