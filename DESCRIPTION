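Package: sbrmab
Title: Macroscopic Modelling of Sequential-Batch Hybridoma Cultures for
    Monoclonal Antibody Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven macroscopic modelling of hybridoma cells grown in
    sequential batch reactors (SBR). Simulates a three-reaction overflow-
    metabolism model (substrate oxidation, glucose overflow to lactate,
    biomass death) with medium-renewal events; identifies the number of
    reactions and the stoichiometric matrix from culture time series by
    maximum-likelihood principal component analysis with chi-square rank
    selection; estimates kinetic and stoichiometric parameters by multistart
    weighted least squares; quantifies parameter uncertainty through forward
    sensitivities, the Fisher information matrix and Monte-Carlo propagation;
    and optimizes the medium renewal time and composition for monoclonal
    antibody production. A synthetic-data generator emulating a sequential
    batch campaign makes every stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
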