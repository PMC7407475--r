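Package: gscope
Title: Recurrent Genomic Selection Simulation with Variance-Preserving
    Parental Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of recurrent genomic-selection breeding
    programs in fully inbred crops. Implements RR-BLUP genomic prediction
    with REML variance components, a sliding training panel updated by the
    tails rule, meiosis and single-seed descent on a multi-chromosome
    genetic map, and four parental selection strategies: truncation
    selection with random mating, the scoping method (marker-variance
    maximizing mate allocation), population-merit selection with a genomic
    relationship penalty, and maximum-variance-total selection. Tracks
    genetic values, QTL allele fixation, genetic variance and prediction
    accuracy across breeding cycles and replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
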