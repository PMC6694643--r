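Package: famline
Title: Familial Aggregation and Liability-Threshold Heritability from
    Matched Case-Control Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the classical genetic-epidemiology analysis of a 1:1
    matched case-control family study of a binary trait: prevalence of the
    trait among relatives stratified by degree of relatedness, the
    modified-Weinberg (singles) segregation ratio with its standard error
    and inheritance-pattern classification, and Falconer liability-threshold
    heritability estimated from the prevalence difference between relatives
    of cases and relatives of controls. Threshold deviates are computed
    exactly from normal theory or taken from a user-supplied lookup table.
    A liability-threshold family simulator with known heritability supports
    validation of every estimator by parameter recovery, and a pipeline
    driver chains roster aggregation, heritability and segregation analysis
    into a single replication report.
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
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
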