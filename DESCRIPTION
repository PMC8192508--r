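Package: agingflow
Title: Signal-Flow Analysis of Aging Methylation and Expression Changes on Signed Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline that converts age-associated DNA-methylation
    changes at CpG positions into transcription-factor input signals, propagates
    them through a signed gene regulatory network by linear signal flow analysis,
    classifies downstream differentially expressed genes by the consistency of
    their predicted direction of activity change, ranks intermediate network
    nodes as candidate reverse-aging control targets, and screens perturbagen
    expression profiles for reversal of the aging signature. Includes a
    synthetic multi-omics cohort simulator with planted ground truth so every
    stage of the pipeline is testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
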