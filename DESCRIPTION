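Package: tcrep
Title: TCR-Beta Immune Repertoire Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for T cell receptor beta-chain (TCR-beta)
    immune repertoire analysis: a ground-truthed VDJ rearrangement and
    sequencing-read simulator, paired-end read merging, germline V/J
    annotation with identity filtering, IMGT-convention CDR3 extraction and
    productivity calling, clonotype frequency tables, highly-expanded-clone
    (HEC) and normalized Shannon entropy diversity statistics, V/J gene-family
    usage profiles and CDR3 length spectratypes, cross-sample shared-clone
    classification, cohort-level group comparison, and multiplex-PCR
    amplification-bias estimation from cycle-series experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    rlang,
    tools,
    dplyr,
    tibble,
    tidyr,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
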