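Package: accessome
Title: Chromatin Accessibility Atlas Construction and Downstream
    ATAC-seq Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a reference atlas ("accessome") of unique,
    non-overlapping accessible regions from ATAC-seq peak sets and
    carries the atlas through the downstream analyses used to study
    chromatin dynamics in developmental lineages: genomic-feature
    annotation with exact two-tailed binomial enrichment, peak-to-gene
    association, negative-binomial likelihood-ratio tests for
    differential accessibility across perturbation/time-course designs,
    threshold-based peak-set and gene-set algebra (including primed
    versus de novo element classification), peak-level gene set
    enrichment analysis with permutation-normalized enrichment scores,
    position weight matrix scanning with exact score thresholds and
    hypergeometric motif enrichment, and chromVAR-style motif
    accessibility deviation Z-scores with GC-matched background peak
    sampling. A seeded synthetic-data generator emulates the lineage x
    condition x timepoint study design so the whole pipeline runs and
    validates without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    MASS,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2,
    optparse
biocViews: Epigenetics, ATACSeq, DifferentialPeakCalling,
    GeneSetEnrichment, MotifAnnotation, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
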