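Package: maxentpop
Title: Maximum-Entropy Modelling of Population Distribution Across
    Territorial Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and forecasts the distribution of a national
    population across territorial units (departments, provinces) by
    maximizing Shannon entropy subject to linear constraints built from
    socio-ecological flow variables (higher-education students as an
    information flow, electricity consumption as an energy flow, water
    demand as a matter flow) and from non-centered moments of the
    reindexed previous-year distribution. Provides a Newton solver for
    the Lagrangian dual of the discrete maximum-entropy problem,
    constraint builders with descending and bell-shaped territorial
    reorderings, a yearly calibration and regression-based forecast
    pipeline with error reporting, and a seeded synthetic panel
    generator (including planted-truth panels for exact recovery
    tests).
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
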