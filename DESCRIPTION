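Package: surgcomm
Title: Surgical Communities from Patient-Flow Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovers natural surgical communities from hospital admissions
    data. Provides a synthetic generator of HES-like elective admissions with
    planted hierarchical geography; preprocessing rules for first-operative-day
    procedure extraction, code exclusions and nearby-site merging; Charlson
    comorbidity scoring and age-based operative risk classification;
    construction of an LSOA-by-provider presentation-proportion matrix, its
    cosine-similarity network and a relaxed-minimum-spanning-tree
    sparsification; multiscale Markov-stability community detection with a
    generalised Louvain optimiser; and per-community supply-demand and
    equivalent-market-size analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    Matrix,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
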