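Package: poolgsi
Title: Informative SNP Selection and Genetic Stock Identification from
    Pooled-DNA Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating population allele frequencies from
    pooled-DNA SNP-array theta values (allelotyping with genotype-cluster
    correction and replicate quality control), summarising population
    structure (expected heterozygosity, Weir-Cockerham F_ST, Delta
    allele-frequency differentials, Nei's D_A distance, neighbor-joining
    trees with bootstrap support), ranking markers by informativeness
    (global/pairwise F_ST, Delta, and a Bayesian F-model outlier scan with
    posterior odds and q-values), and quantifying how many markers a
    genetic stock identification baseline needs via simulated
    baseline/mixture genotypes, Rannala-Mountain assignment with EM
    mixture estimation, and exponential marker-requirement curves. A
    synthetic-data generator with known truth supports end-to-end testing
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
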