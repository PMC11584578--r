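Package: tribetools
Title: RNA-Editing-Based RBP Target Mapping for Bulk and Single-Cell TRIBE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end analysis workflow for TRIBE experiments
    (Targets of RBPs Identified By Editing), in which an RNA-binding protein
    fused to the ADAR catalytic domain deposits A-to-I edits on bound
    transcripts. Covers UMI-aware edit-site pileup from tagged alignments,
    transcript-strand calibration and known-variant masking, a beta-binomial
    background model fitted on ADAR-only controls with a four-part
    significance filter, construction and quality control of the per-cell
    editome (genes-by-cells edited-UMI matrix), binding-intensity
    normalization, editome clustering and positive-population selection,
    differential-binding analysis with expression-dependence classification
    and relative binding intensity, spline likelihood-ratio tests for
    binding dynamics along a supplied pseudotime, and known-motif enrichment
    and CLIP-peak flank profiling. Ships a ground-truthed synthetic-data
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    VariantAnnotation,
    igraph,
    MASS,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
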