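Package: scArchetypes
Title: Longitudinal Pathway Archetype Analysis for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking tumor cell states across serial biopsies from
    single-nuclei RNA-seq. Implements per-cell single-sample gene-set
    enrichment (ssGSEA) scoring, ordinary-least-squares temporal modeling of
    pathway and gene dynamics across treatment cycles with Benjamini-Hochberg
    control, SVD reduction of pathway-score space with batch-component
    removal, consensus-clustering K selection by the proportion of ambiguous
    clustering (PAC), shared-nearest-neighbor Louvain clustering into
    archetypes with Wilcoxon differential-pathway profiles and per-cycle
    proportion tracking, and an AUC-gated rank-correlation classifier that
    rescues ambiguous copy-number-based malignancy calls. A negative-binomial
    cohort simulator with planted archetypes, temporal trends, batch shifts
    and copy-number segments provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    limma,
    igraph,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneSetEnrichment, Clustering,
    TimeCourse, Classification
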