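Package: EvoShock
Title: Microevolution Analysis of Bacterial Ethanol Shock and Adaptation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for tracking microbial microevolution
    from transient stress (shock) to inheritable tolerance (adaptation)
    using paired transcriptomic and genomic evidence. Provides
    differential-expression calling on replicated log2-ratio expression
    data with joint fold-change and Z-score cutoffs, transcriptome
    state-space analysis (Pearson-correlation distances among absolute and
    relative cellular states, bootstrap-supported hierarchical clustering,
    and quantitative microevolution metrics: distinctness, discreteness,
    resilience, memory and convergence), differential co-expression
    network inference with random-matrix-theory spectral thresholding and
    fast-greedy modularity module detection, dynamic operon detection from
    RNA-seq coverage steps and paired-end bridging evidence, and genome
    mutation analysis (multi-caller consensus, codon-level effect
    annotation, pooled-population allele frequencies with a beneficial
    candidate rule, and the per-genome per-generation mutation rate). A
    synthetic-data module generates every input with planted ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
biocViews: Transcriptomics, NetworkInference, Genetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
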