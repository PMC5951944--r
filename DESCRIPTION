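Package: bidiCAGE
Title: Discovery of Bidirectional Enhancer RNA Loci from CAGE Transcription Start Site Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting candidate enhancer RNA (eRNA) loci
    from stranded CAGE 5' tag counts (CTSS tables). Pools per-sample CTSSs into
    non-overlapping strand-specific consensus TSS clusters, performs count-based
    differential expression between two conditions with TMM normalization, a
    conditional negative-binomial exact test and Benjamini-Hochberg FDR, pairs
    divergent minus/plus clusters within 300 bp into bidirectional loci,
    classifies them by per-strand fold-change and significance, and annotates
    loci against a protein-coding gene model (promoter/UTR/exon/intron/
    downstream/distal-intergenic) with enhancer-set overlap. Ships a synthetic
    CAGE data generator with planted ground truth so every stage is exercised by
    recovery tests at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
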