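Package: classair
Title: Classroom Air Quality Analysis for HEPA Filter Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing indoor air quality interventions in schools
    impacted by roadway and aircraft pollution. Estimates outdoor air-exchange
    rates from CO2 tracer-decay experiments, quantifies infiltration of outdoor
    ultrafine particles and black carbon into classrooms via windowed
    indoor/outdoor ratios, estimates portable HEPA filter removal effectiveness
    by ratio and by lagged log-log regression, and counts near-school flight
    operations with an altitude/radius geofence. Includes a single-zone
    mass-balance simulator with known ground truth so every pipeline stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
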