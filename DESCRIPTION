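Package: gammarep
Title: Chicken TCR Gamma Repertoire Analysis from 5'RACE Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for T cell receptor gamma (TRG)
    repertoire analysis in the chicken, from pooled 5'RACE amplicon reads
    through barcode demultiplexing, V/J gene segment assignment and
    Smith-Waterman CDR3 junction extraction, to TRGV usage profiles with
    hierarchical bootstrap confidence intervals, coverage-standardised
    Hill-number diversity, public/private clonotype analysis across birds
    and lines, and regression of TRGV usage on recombination signal
    sequence quality. Ships a curated germline TRG locus model, an
    in-silico PCR/restriction-digest tool for locus structure validation,
    and a ground-truthed repertoire simulator so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
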