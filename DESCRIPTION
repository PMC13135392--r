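Package: regshift
Title: Regulatory-Shift Analysis of TF Footprints, Motif Deviations and
    Gene-Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of base-resolution chromatin contribution
    tracks and single-cell multiome matrices: motif seqlet footprinting and
    profile clustering on contribution scores, bias-corrected motif deviation
    z-scores with GC-matched backgrounds, eRegulon AUC scoring with
    pseudo-bulk correlation filtering and regulon specificity scores,
    ridge-regression gene-regulatory networks with in-silico transcription
    factor knockout and overexpression, and hypergeometric and Monte-Carlo
    gene-set overlap statistics. Ships a seeded synthetic-data generator with
    planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
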