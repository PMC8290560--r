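Package: rregg
Title: Random-Regression Genetic Evaluation of Egg-Production Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based (RR-PBLUP) and single-step genomic (RR-ssGBLUP)
    random-regression evaluation of weekly egg production over a 24-week
    laying trajectory. Provides normalized Legendre trajectory bases and
    covariance-function tools, numerator relationship matrices and their
    sparse inverses, VanRaden genomic relationships with blending and
    single-step H-inverse assembly, sparse mixed-model equations with direct
    and preconditioned conjugate-gradient solvers, Gibbs sampling of
    random-regression variance components with heterogeneous residuals,
    forward-validation accuracy and Mendelian-sampling variance-ratio
    statistics, and a calibrated simulator of pedigree, SNP genotypes and
    weekly egg records for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
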