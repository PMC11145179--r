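Package: spatialTME
Title: Spatial Tumor-Microenvironment Analysis for Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell spatial data from multiplexed tissue
    imaging (imaging mass cytometry) of tumor microarrays. Provides rule-based
    marker positivity and cell phenotyping, tumor-nest/stroma compartment
    density profiling, consensus-clustering classification of tumor
    microenvironments into four classes with automatically derived decision
    cutoffs, cellular community detection from windowed neighbor composition,
    an alpha-smooth-muscle-actin-positive fibroblast barrier score on
    k-nearest-neighbor cell graphs, permutation tests for cell-cell
    interaction and avoidance, intratumor heterogeneity statistics, and a
    synthetic tissue-core generator with planted ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
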