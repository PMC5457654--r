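Package: pedsda
Title: Signal Detection Analysis of Pedestrian Injury Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies subgroups of pedestrians at elevated risk of severe
    injury by signal detection analysis: recursive binary partitioning of an
    injury registry on the variable and cut-point maximising a weighted kappa
    agreement with the severity outcome, gated by a chi-square test and a
    kappa confidence interval, with the classical three stopping rules
    (minimum subgroup size, significance, CI sign). Includes residence-to-
    injury-site Euclidean and road-network shortest-path distances, group
    comparison and subgroup cross-validation tables, and a synthetic
    injury-registry generator with a planted subgroup structure for
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
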