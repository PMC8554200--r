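Package: hlvqtl
Title: Mapping QTLs for Interspecific Interactions with Holling Type II
    Lotka-Volterra Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Functional (systems) mapping of quantitative trait loci that
    govern interspecific interactions between two co-cultured microbial
    species. Growth trajectories in monoculture and co-culture are modelled
    by coupled logistic equations extended with a Holling type II functional
    response, embedded in a genotype-specific bivariate longitudinal normal
    likelihood with first-order structured antedependence (SAD(1))
    covariance. Provides likelihood-ratio genome scans over one or two
    genomes, permutation and Bonferroni chi-square thresholds, partitioning
    of genotypic values into direct, indirect and genome-genome epistatic
    effect curves with variance curves, classical growth-model comparison by
    information criteria, and a heritability-calibrated simulator with a
    power and false-positive-rate study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
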