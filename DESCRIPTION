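Package: allergotype
Title: Bayesian Clustering and Longitudinal Tracking of Allergen Component IgE Sensitization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering cross-sectional clusters of allergen
    component IgE responses with a collapsed Bayesian Bernoulli mixture model
    of unknown order, sampled by an allocation sampler embedded in
    Metropolis-coupled MCMC. Includes ECR (Equivalence Classes
    Representatives) relabeling of allocation samples, longitudinal
    cluster-flow tracking across ages, logistic-regression association of
    cluster sensitization with allergic outcomes, panel input/output with
    activity and drop-out annotation, and a synthetic longitudinal cohort
    generator so that every pipeline stage is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
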