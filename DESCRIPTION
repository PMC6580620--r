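Package: mirstrat
Title: Small RNA-Seq miRNA Quantification, Subtyping and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mature-miRNA expression analysis from
    aligned small RNA-seq reads: coordinate-deviation read assignment with
    multi-mapper rescue, cross-version isoform remapping, log2-CPM
    normalization, differential-expression signature construction,
    consensus clustering with item consensus and delta-area model
    selection, reference-centered nearest-centroid intrinsic-subtype
    classification, and median-split Kaplan-Meier survival stratification.
    Ships a synthetic-data module that generates annotation, alignments,
    expression cohorts and survival records with known ground truth so
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    survival,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
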