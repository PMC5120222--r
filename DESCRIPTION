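Package: icmcensus
Title: Single-Cell Lineage Census of the Mouse Blastocyst Inner Cell Mass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-cell
    immunofluorescence censuses of the preimplantation mouse blastocyst.
    Generates synthetic embryo cell tables with stage-dependent lineage
    structure (epiblast, primitive endoderm, double-positive progenitors,
    double-negative late epiblast), corrects depth-dependent fluorescence
    decay by per-embryo log-linear regression with empirical-Bayes slope
    shrinkage, classifies inner-cell-mass cells by fixed-threshold quadrants
    or reference-anchored k-means in log marker space, summarises lineage
    composition by developmental stage with local-regression trends, and
    simulates FGF-pathway modulation experiments together with a
    progenitor-pool predictor of treatment outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
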