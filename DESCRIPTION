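Package: replivar
Title: Between-Replicate Gene Expression Variability and Growth
    Variability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for calling genes with high between-replicate
    expression variability from FPKM tables (absolute log2 divergence,
    reference top-percentile cutoff, overlap and correlation summaries)
    and for quantifying growth variability in seedling populations
    (coefficient of variation, Levene's variance-homogeneity test,
    Mann-Whitney U, adjusted rank transform factorial test, qRT-PCR
    relative scaling). Includes seeded synthetic-data generators that
    emulate the replicate structure and trait populations the analysis
    assumes, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
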