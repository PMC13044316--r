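Package: vesiclust
Title: Quantification of Late-Endosome/Lysosome Clustering from Fluorescence Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial clustering of late endosomes/lysosomes
    (LE/Lys) in fluorescence microscopy images through a per-cell clustering
    index: the proportion of segmented vesicles in direct contact with at
    least one other vesicle. Provides a synthetic scene generator with known
    ground truth (diffraction-blurred vesicle disks, Poisson-Gaussian camera
    noise, dispersed and perinuclear-clustered presets), classical
    weight-free segmentation (Laplacian-of-Gaussian markers with seeded
    watershed for vesicles, nucleus-seeded territories for cells), an
    object-adjacency contact graph, two-channel Pearson colocalization with
    a Costes-style automatic threshold, and hierarchical superplot
    statistics (Student's t, one-way ANOVA, Tukey HSD, Monte-Carlo Dunnett)
    over cells nested in independent experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse
biocViews: CellBiology, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
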