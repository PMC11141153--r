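Package: atriomics
Title: Endolysosomal Multi-Omics Analysis for Atrial Fibrillation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used in
    endolysosomal multi-omics studies of large-animal atrial fibrillation
    models: permutation-FDR differential proteomics with an S0-moderated t
    statistic, rank-based multi-dataset pathway-enrichment MANOVA integrating
    proteomics and transcriptomics, automated glycogen-granule counting in
    electron micrographs, and fluorometric enzyme-assay and Western-blot
    summary statistics. A synthetic-data generator with known ground truth
    (regulated proteins, regulated pathways, planted granules, true enzyme
    activities) makes every stage testable without access to deposited raw
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Transcriptomics, Pathways, DifferentialExpression,
    CellBiology
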