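Package: isoga
Title: Manifold-Aware Genetic-Algorithm Gene Selection for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper gene selection for "large p, small n" expression matrices.
    A fixed-cardinality genetic algorithm searches gene subsets whose Isomap
    embedding minimises the Davies-Bouldin cluster-validity index; repeated
    searches over stratified bootstrap bags are aggregated through a binomial
    non-randomness threshold into a final gene set. Includes classical
    multidimensional scaling and no-embedding ablations, maximum-likelihood
    intrinsic-dimension estimation, information-gain prefiltering with
    MDL discretisation, nested cross-validation with macro/micro AUC, and a
    synthetic-data generator with planted nonlinear class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
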