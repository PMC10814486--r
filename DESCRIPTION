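Package: genomechaos
Title: Entropy, Ergodicity and Clonal Selection Models of Genome Chaos
    in Cancer Cell Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative models of genome chaos driven by chromothripsis
    in cancer cell populations: Monte Carlo simulation of per-nucleotide
    somatic mutation and the waiting time to a first mutation in a coding
    sequence, Shannon entropy of chromosomal rearrangement, a Gibbs-type
    stability criterion with a critical mutagenicity threshold, a
    chromothripsis mixture model for the effective population mutation
    rate, a discrete ergodicity-defect statistic over clone distributions
    of micronucleus frequency, and a seedable clonal-selection simulator
    with an apoptosis threshold that emulates artificial selection of
    rhabdomyosarcoma clones for increasing karyotype instability. All
    results are returned as tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
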