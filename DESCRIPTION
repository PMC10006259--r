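Package: forageGS
Title: Genomic Selection Toolkit for Outbreeding Forage Grass Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genomic selection analysis for obligate-outbreeding forage
    grasses such as perennial ryegrass: genotype quality control with
    linkage-disequilibrium k-nearest-neighbour (LD-kNN) imputation, BayesA
    whole-genome regression by Gibbs sampling with narrow-sense heritability
    estimation, genomic estimated breeding value (GEBV) accuracy evaluation by
    k-fold cross-validation, forward prediction across years and prediction
    from pooled allele-frequency reference populations, phenotype descriptive
    statistics, and simulation of 4-parent synthetic-variety groupings under
    GEBV selection windows. Includes a synthetic-population generator with
    known trait architectures for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
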