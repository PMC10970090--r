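Package: zolnet
Title: Shared-Patient Network Analysis of Sedative-Hypnotic Prescription Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study doctor-shopping for zolpidem (a controlled
    non-benzodiazepine hypnotic) in outpatient claims data. Provides a seeded
    synthetic claims generator emulating a county-level cohort of chronic
    zolpidem users, flowchart-style cohort selection with attrition tracing,
    Defined Daily Dose (DDD) based classification into low- and high-dose
    users (360-tablet annual threshold), construction of directed
    shared-patient institution networks with density, in-degree and
    betweenness centrality, multivariable logistic regression of high-dose
    membership with optional stepwise selection and adjusted odds ratios,
    and an end-to-end pipeline that renders descriptive tables, attrition
    tables, per-group network metrics and GraphML exports.
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
    igraph,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
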