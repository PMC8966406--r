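Package: gselsim
Title: Forward-in-Time Simulation and Genomic Prediction for Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward-in-time stochastic simulator for livestock breeding
    populations (historical drift-mutation phase, expansion, and recent
    generations under pedigree-BLUP selection) together with six genomic
    breeding-value estimation methods (GBLUP, single-step GBLUP, BayesA,
    BayesB, Bayesian ridge regression, and the Bayesian LASSO) and the
    machinery to evaluate prediction accuracy across marker densities, QTL
    numbers, reference-population sizes and sex compositions, including
    fixed-effects ANOVA with Duncan's multiple range test. Meiosis uses a
    stationary gamma-renewal crossover process with interference; genotypes
    are exchanged as PLINK PED/MAP text files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    data.table,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
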