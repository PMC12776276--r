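Package: retinotopo
Title: Topographic Reconstruction of Retinal Gene Expression from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs two-dimensional topographic maps of gene expression
    in the developing retina from dissociated single-cell RNA-seq data.
    Cells are positioned along the dorso-ventral and naso-temporal axes by
    marker-based module scores, binned into regular spatial grids, smoothed
    and clipped into per-gene expression maps. Spatially patterned genes are
    detected with a permutation Moran's I test, clustered around greedy
    anchor genes by cosine similarity, and tested for regional differential
    expression with pseudobulk negative-binomial models. A companion image
    module quantifies multiplexed RNA-FISH flat-mount images into aligned
    block heatmaps and one-dimensional intensity profiles for cross-modal
    comparison, and a synthetic-data module generates datasets and images
    with known spatial ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
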