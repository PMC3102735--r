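Package: zgatools
Title: Motif Enrichment, Activation Scoring and Expression Analysis for
    Zygotic Genome Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transcriptional activation at the
    maternal-to-zygotic transition. Extracts promoter windows from genome
    sequence and annotation, scans sequence sets for degenerate IUPAC
    consensus binding motifs, tests motif counts against a compositional
    binomial null model (expected count, standard deviation, Z-score,
    normal and exact binomial p-values), detects clusters of binding
    sites, converts literature-evidence tables into weighted
    activator-target maps with cumulative activation scores, and analyses
    expression tables for fold-change regulation calls, gene-category
    composition, set overlap and a permutation gene-set enrichment
    statistic. Synthetic generators with known ground truth make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
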