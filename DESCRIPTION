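Package: broadbins
Title: Binned Analysis of Broad Histone Marks from ChIP-Seq and CUT&RUN/TAG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-agnostic analysis of broad histone post-translational
    modifications (H3K36me2, H3K27me3, H3K9me3, ...) from ChIP-Seq or
    CUT&RUN/TAG read counts binned in uniform genomic windows. Reads binned
    BED signal, filters blacklisted and low-count bins, normalizes by library
    size with optional input correction, median-ratio or TMM factors and
    quantitative (spike-in or mass-spectrometry) scaling, and writes bigWig
    tracks. Provides replicate diagnostics (PCA, correlation clustering),
    genic/intergenic bin classification and scatterplots, density-based
    (HDBSCAN) clustering of bins in two-sample signal space, per-bin
    differential binding with a reproducibility-optimized t-type statistic
    (bootstrap-optimized, permutation FDR), stratified Fisher region-set
    enrichment, and a negative-binomial simulation/benchmark framework with
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    jsonlite
Config/testthat/edition: 3
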