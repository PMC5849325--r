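Package: lgpnet
Title: Linear Genetic Programming and Synergy Networks for Case-Control Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves register-machine linear genetic programming (LGP)
    classifiers to predict case/control status from metabolite concentration
    profiles, then mines the resulting ensemble of best models for effective
    features: per-feature occurrence and pairwise co-occurrence counts across
    models, construction of a metabolite synergy network from the top
    co-occurring pairs with hub/bottleneck (closeness/betweenness) statistics,
    and a two-round reduced-feature replication procedure with a logistic
    regression baseline. Includes a synthetic case-control metabolomics
    generator with batch effects, covariate effects and planted non-linear
    synergies, plus the standard preprocessing chain (mean-ratio batch
    correction, covariate residualization, stratified discovery/replication
    split, z-score normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
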