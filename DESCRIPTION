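Package: promloop
Title: Alternative-Promoter Usage, Enhancer Looping and Epigenetic State
    of Multi-Promoter Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for dissecting the regulation of genes
    driven by multiple alternative promoters, modelled on the cancer-active
    alternative promoter of the human myoglobin (MB) gene. Quantifies
    start-exon-specific transcript abundance (RPKM) from RNA-Seq alignments
    and TSS-proximal nascent transcription from GRO-Seq, computes condition
    fold changes with one-way ANOVA and Tukey-Kramer post-hoc tests, calls
    ChIP-Seq peaks in fixed windows with an automatically derived Poisson
    minimum-read threshold and input-control correction, classifies
    differential enrichment with a negative-binomial exact test, integrates
    promoter-anchored ChIA-PET interaction pairs into named candidate
    enhancer regions, builds a cross-assay cross-condition evidence matrix,
    scans candidate regions for hormone- and hypoxia-response element
    consensus motifs, and calls per-CpG methylation states from bisulfite
    counts. A synthetic-data generator with planted ground truth exercises
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
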