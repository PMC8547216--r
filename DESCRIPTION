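Package: comorbidnet
Title: Disease-Disease Association Discovery from Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers disease-disease association networks from longitudinal
    electronic health record diagnosis streams. Maps ICD-9/ICD-10 codes to
    single-level CCS categories, orders each patient's diagnoses
    chronologically, learns 32-dimensional code embeddings with a built-in
    CBOW word2vec trainer (negative sampling, single-threaded,
    deterministic), extracts correlation-thresholded comorbidity networks,
    clusters diseases hierarchically, and characterises directional time
    delays between first diagnoses of strongly associated disease pairs.
    Includes a seeded synthetic cohort generator with planted comorbidity
    clusters and directional lags so every stage is verifiable without
    access to protected registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
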