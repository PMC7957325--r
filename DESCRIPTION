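Package: germfate
Title: Germline Versus Somatic Divergence Analysis for Zebrafish PGC Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the divergence between zebrafish primordial
    germ cells (PGCs) and somatic cells across early development. Implements
    zygotic-gene classification from staged TPM profiles, ERCC spike-in
    absolute RNA quantification, an intron-retention statistic with a
    permutation significance test, Tn5-corrected ATAC-seq cut-site processing
    with a Poisson peak scan, a copula-mixture irreproducible discovery rate
    (IDR) filter, a candidate-enhancer filtering cascade, PCA and
    self-organizing-map clustering of accessibility signal, CpG methylation
    summarization with per-CpG exact testing, and a germ-granule/nucleus
    contact-ratio score. A seeded synthetic-data module emulates the study
    design (two cell types, five stages, two replicates) with ground-truth
    labels so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
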