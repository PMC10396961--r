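Package: woodcarbon
Title: Carbon Bookkeeping for Global Wood Harvest Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bookkeeping simulator for the carbon consequences of wood
    harvest. Tracks per-hectare carbon across live biomass, slash, dead
    roots, wood products and landfills under harvest and no-harvest paths,
    values the resulting annual atmospheric changes as harvest-year
    equivalent emissions with time discounting, projects national wood
    demand with a log-transformed fixed-effects panel model, allocates
    projected demand to plantation and secondary-forest supply under
    alternative scenarios, and reports time-discounted carbon costs,
    clear-cut-equivalent harvest areas and fossil substitution benefits.
    Includes a synthetic-data generator so the full pipeline runs and
    tests without any external download.
License: MIT
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
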