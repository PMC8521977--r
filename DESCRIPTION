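Package: incembed
Title: Disease Incidence Estimation from Language-Embedding Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and country-specific disease incidence from
    contextual entity embeddings. Provides loaders for precomputed word- and
    entity-level embedding tables, bag-of-words sentence aggregation
    (element-wise min/max/mean) and provider fusion, feature assembly over
    incidence tables (log10 targets, one-hot age bands), three leave-out
    cross-validation schemes (held-out disease-country pairs, unseen
    countries, unseen diseases), a funnel multilayer-perceptron regressor
    with batch normalization trained by Adam alongside global-average, ridge
    and one-hot baselines, log-space error metrics including an inter-group
    concordance statistic, repeated linear-SVM experiments that score how
    much group structure an embedding carries, and a synthetic-world
    generator so the whole pipeline is testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
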