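Package: mitopink
Title: Quantitative Analysis of PINK1 Transmembrane-Variant Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative assays used to characterise
    transmembrane variants of the mitochondrial kinase PINK1. Provides a
    synthetic confocal-scene generator with full ground truth; a
    mitochondrial-enrichment quantification pipeline (maximum-intensity
    projection, wide-Gaussian background correction, Otsu segmentation of
    cell and mitochondria, mask-ratio statistic with quality control);
    skeleton-based mitochondrial network morphology (branch lengths,
    footprint, network counts); internally quenched fluorogenic protease
    assay analysis with Michaelis-Menten fitting and catalytic-efficiency
    comparison; transmembrane helix tilt-angle analysis of trajectory
    frames; and the group statistics used alongside these assays
    (Brown-Forsythe one-way ANOVA, Sidak adjustment, paired t tests,
    reference normalisation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    tiff,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Proteomics, Software
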