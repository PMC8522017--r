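Package: topictrends
Title: Temporal Topic Trends in Literature Abstract Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Latent Dirichlet allocation topic modelling of abstract corpora
    with a seed-deterministic collapsed Gibbs sampler, coherence-based
    selection of the topic count, weekly temporal topic-trend extraction by
    per-bin document concatenation, and category subdivision via Hellinger,
    Jaccard and normalized Euclidean distance comparisons. Includes readers
    for Medline-dialect, JSONL and CSV abstract records with the standard
    exclusion filters, a bag-of-words preprocessing pipeline with bigram
    merging, and a synthetic corpus generator with known topics, temporal
    trajectories and category structure for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
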