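Package: gxepred
Title: Genomic Prediction Across Environments with Genotype-by-Environment
    Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genomic prediction of breeding values in two related
    livestock populations raised in different environments. Implements
    genotype quality control, linkage-disequilibrium statistics and
    between-population LD consistency, the VanRaden genomic relationship
    matrix, pedigree BLUP with REML variance components and corrected
    phenotypes, single- and multi-trait GBLUP (environment as trait),
    single- and multi-trait BayesC-pi Gibbs samplers, and a replicated
    cross-validation harness comparing single-population, combined-population
    and multi-trait prediction schemes. A two-population simulator with
    drifted linkage disequilibrium and environment-correlated QTL effects
    provides fully synthetic test data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
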