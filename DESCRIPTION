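Package: bpshift
Title: Cryptic 3' Splice Site and Alternative Branchpoint Analysis for
    SF3B1-Mutant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises the cryptic 3' splice sites (AG')
    activated by SF3B1 hotspot mutations from splice-junction read counts.
    Provides junction BED parsing, a negative-binomial differential
    junction-usage test with Benjamini-Hochberg correction, alternative
    acceptor/donor event classification with distance and 3-nt periodicity
    statistics, splice-acceptor sequence-context matrices and +1 nucleotide
    composition contrasts, branchpoint candidate enumeration and scoring by
    U2 snRNA base-pairing potential with BP/BP' assignment, a mechanistic
    softmax model of AG versus AG' choice as a function of the mutant
    transcript fraction (including in-silico branchpoint mutagenesis), and a
    seeded synthetic-cohort generator that plants the full signature so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
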