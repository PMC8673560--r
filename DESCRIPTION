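Package: airwaymorph
Title: Morphometry of Embryonic Airway Branching Under Transpulmonary Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of early lung branching
    morphogenesis in explant culture under controlled transpulmonary
    pressure. Provides a seeded generator of ground-truth embryonic airway
    trees with canonical murine lineage labels (Tr, R, L, RCd, RAc, RMd,
    RCr, L1-L5), voxel rasterization of trees into binary confocal-style
    volumes, topology-preserving 3D skeletonization with distance-transform
    radius estimation, branch lineage annotation, whole-lung morphometry
    (basal surface area, lumen-inclusive volume, terminal branch counts,
    fold-changes), allometric power-law scaling analysis with bootstrap
    confidence intervals, and a steady-state diffusion-consumption model of
    oxygen in the culture-medium column.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    tidyr,
    ggplot2,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
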