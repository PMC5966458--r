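Package: invadoLCM
Title: Laser-Capture Microdissection Targeting and SILAC Proteomics of
    Invadosome Rosettes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to automate the targeting of invadosome rosettes for
    laser-capture microdissection and to post-process the resulting
    SILAC proteomics data. Fluorescence fields are segmented with the
    classical ImageJ-style operator chain (red-channel split, disk
    median, rolling-ball background subtraction, automated thresholding,
    closing and hole filling, particle analysis with area and
    circularity filters), segmented regions are converted into
    calibrated stage-coordinate dissection plans with adjacent-field
    tiling, high-content phenotypes (rosettes per nucleus, gelatin area
    degraded per cell) are quantified with one-way ANOVA and Bonferroni
    post tests, and peptide identification tables are split into
    13C-labelled and contaminating peptides before label-free
    enrichment calling at a rosette/total ratio of at least 1.5.
    Seeded synthetic-data generators for rosette fields, in situ
    zymography pairs and SILAC peptide tables make the whole pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    xml2,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
biocViews: Software, CellBiology, Proteomics, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
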