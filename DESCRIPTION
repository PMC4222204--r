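Package: msatpop
Title: Microsatellite Population Genetics: Differentiation, Outlier Scans,
    Admixture Clustering and Demographic Scenario Choice
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for codominant microsatellite genotype data: GenePop and
    tabular input/output, per-population diversity statistics (allele counts,
    effective alleles, observed and unbiased expected heterozygosity),
    pairwise and grouped differentiation (Nei-Chesser GST, Hedrick's
    standardized F'ST, Jost's D) with permutation tests and bootstrap
    intervals, FDIST-style FST-outlier detection against a coalescent
    island-model null envelope, Bayesian admixture clustering with Evanno
    delta-K model selection, and approximate Bayesian computation over
    divergence-with-bottleneck demographic scenarios using a generalized
    stepwise mutation coalescent simulator. Includes a calibrated synthetic
    genotype generator emulating a two-group, fourteen-population study
    design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
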