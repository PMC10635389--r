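Package: senoglia
Title: Morphometric and Spatial-Transcriptomic Quantification of Aged White-Matter Microglia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for senescent and disease-associated
    microglia in aged white matter. Provides segmentation-derived
    morphometrics (feret-axis tract alignment, corrected total cell
    fluorescence, density, marker stratification, midline/edge distance
    statistics, a PCA composite phenotyping index), a single-cell spatial
    transcriptomics pipeline (per-cell QC, normalization, highly variable
    gene selection, PCA/kNN, Leiden clustering, microglia marker gating,
    macrophage exclusion, transcript-count enrichment classes, Wilcoxon and
    Gini marker detection, subclustering), and bulk expression utilities
    (delta-delta-Ct relative expression, negative-probe LOQ filtering, third
    quartile normalization). A synthetic-data module generates tissue
    sections and count matrices with planted group effects so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
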