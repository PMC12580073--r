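Package: firecarbon
Title: Carbon Accounting for Wildfire-Mitigation Treatments in Mixed-Conifer Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stock-change carbon accounting for repeated forest plot
    inventories in a before-after-control-impact (BACI) fuel-treatment
    experiment. Converts tree, snag, understory, fuel-transect, litter/duff
    and soil records into per-plot carbon pools (planar-intercept fuel
    loads, allometric tree biomass, depth-to-biomass conversions), builds
    net-ecosystem carbon balance and productivity ledgers with prescribed
    fire emission and harvest removal entries, tracks harvested carbon
    through the long-lived wood product chain, computes wildfire-resistant
    and stable carbon metrics under a simulated wildfire, estimates
    interval recovery rates and BACI contrasts with bootstrap uncertainty,
    and discounts annual treatment-minus-control flux differences into a
    cumulative carbon cost. Ships a seeded synthetic-experiment generator
    emulating a 12-unit, 4-treatment thinning/mastication/prescribed-fire
    study so the full pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    generics,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
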