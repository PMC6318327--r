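Package: TEmetagene
Title: Metagene Analysis of Transposable-Element Chromatin and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies chromatin-mark and chromatin-modifier enrichment at
    transposable-element (TE) types treated as metagenes, builds the
    bipartite mark-TE relational network, estimates TE age from RepeatMasker
    divergence by the Jukes-Cantor model, calls TE-type expression and
    chromatin-accessibility changes after chromatin-modifier knockdown, and
    scores 2C-like gene-expression signatures. Ships a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
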