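Package: cattleGP
Title: Genomic Prediction for Beef Cattle Traits with GBLUP and the Bayesian Alphabet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genomic-selection analysis toolkit for quantitative traits in
    beef cattle. Provides genotype input/output (PLINK RAW and minimal VCF),
    variant quality control (minor allele frequency, call rate,
    Hardy-Weinberg equilibrium, windowed LD pruning), the VanRaden genomic
    relationship matrix, REML estimation of variance components and
    heritability under the animal model, and five whole-genome regression
    predictors: GBLUP and Gibbs samplers for BayesA, BayesB, BayesCpi and
    BayesR. Predictors are evaluated by k-fold cross-validation with
    predictive ability, heritability-scaled accuracy, inflation slope and
    mean squared error. A synthetic-data module simulates genotypes with
    tunable allele frequencies, missingness and local linkage
    disequilibrium, marker effects under normal, point-normal and
    four-component mixture architectures, and phenotypes with fixed effects
    and a target heritability, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
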