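Package: clademodels
Title: Clade Models of Codon Evolution and Divergent Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood analysis of protein-coding sequence
    alignments with site-class mixture models of the
    nonsynonymous-to-synonymous rate ratio (dN/dS): the site models M0,
    M1a, M2a_rel and M3, branch and branch-site models, and clade models
    C and D with two or more tree partitions. Provides nested likelihood
    ratio tests, AIC model weighting, empirical-Bayes identification of
    divergently evolving codons, per-branch dN and dS, a codon-alignment
    simulator with known site-class labels, and a simulation-based
    calibration study of the multi-clade clade-model likelihood ratio
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
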