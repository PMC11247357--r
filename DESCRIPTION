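Package: dustcase
Title: Dust Storm Days from Speciated Particulate Monitoring and
    Case-Crossover Analysis of Emergency Department Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying short-term health effects of dust storms
    when exposure comes from an intermittent (1-in-3 or 1-in-6 day)
    speciated aerosol monitoring network. Implements a five-criteria
    dust-storm-day classifier on speciated PM measurements (mass,
    coarse/fine split, crustal elements, anthropogenic species, crustal
    enrichment factors), distance-buffer linkage of ZIP units to
    monitors, ICD-9/ICD-10 outcome ascertainment of emergency department
    visits, a customized time-stratified case-crossover design (strata of
    4 days at 6-day intervals inside 24-day blocks), and weighted
    conditional logistic regression fit by Newton-Raphson with analytic
    derivatives, reporting lag-specific odds ratios with Wald intervals.
    Includes synthetic-data generators for all input streams with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
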