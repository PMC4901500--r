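Package: gwpbart
Title: Genome-Wide Phenotype Prediction with Bayesian Additive Regression Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric genome-wide prediction of quantitative phenotypes
    from SNP dosage data using Bayesian additive regression trees (BART):
    a sum of small regression trees with regularization priors, sampled by
    Bayesian backfitting Markov chain Monte Carlo, with variable inclusion
    proportions and partial dependence functions for locus discovery.
    Includes reference predictors (GBLUP, Gaussian-kernel RKHS regression and
    random forests with out-of-bag permutation importance), cross-validated
    mean squared prediction error benchmarking with hyperparameter grids, and
    a pedigree-based QTLMAS2010-style simulator of linked SNP genotypes and
    phenotypes under additive, dominant, over- and under-dominant, epistatic
    and paternally imprinted gene action.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
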