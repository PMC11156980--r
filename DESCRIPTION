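Package: osmapr
Title: Orientation-Selectivity Map Analysis for Retinal Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mapping orientation selectivity across the
    retina from population calcium imaging of responses to moving bars.
    Computes per-cell tuning summaries (response quality index, vector-sum
    direction and orientation tuning, DSI/OSI and preferred angles), decides
    selectivity by a block-shuffled permutation test, discovers functional
    subtypes by k-means with silhouette analysis, computes map-level
    statistics (orientation histograms by retinal region, deviation from the
    ventral axis versus distance from the optic nerve, vector flow fields,
    regional distribution comparisons), and fits a concentric circle/ellipse
    geometric model of how preferred orientation varies with retinal
    location. A synthetic-retina generator provides ground-truth data with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    cluster,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
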