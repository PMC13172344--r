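Package: chromoff
Title: Chromatin-Context Analysis of CRISPR Off-Target Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how chromatin context shapes CRISPR off-target
    editing on endogenous genomes. Scans a reference genome for repeat-rich
    candidate protospacers with an eight-step filter, enumerates
    sequence-similar potential off-target sites (Hamming distance over the
    full protospacer + PAM), groups sequence-identical sites into off-target
    "types", extracts observed edits from somatic-style variant calls, scores
    thirteen chromatin features over 50-bp site windows, screens each type for
    chromatin/editing association with exact or approximate Wilcoxon rank-sum
    tests, and trains tree-ensemble models predicting off-target editing from
    75 sequence + chromatin features. Includes a fully seeded synthetic-data
    generator (toy genomes with planted repeat families, chromatin tracks,
    and simulated edits) so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    xgboost
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
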