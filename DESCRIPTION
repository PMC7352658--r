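Package: pcnslMultimodal
Title: Sex-Stratified Multimodal Analysis of Primary CNS Lymphoma Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multimodal analysis of primary CNS lymphoma (PCNSL)
    cohorts: immunohistochemistry (IHC) cell scoring from brightfield tissue
    images via H-DAB colour deconvolution, dual Phansalkar/Otsu thresholding
    and watershed splitting; spatial immune-density heatmaps from cell
    centroids; MR-segmentation volumetrics, focus counting and atlas-based
    location percentages; sex-stratified Ward clustering with iterative
    random-forest imputation; and survival modelling (Kaplan-Meier, log-rank,
    recursive-partitioning cutoffs, backward-eliminated Cox models). A
    synthetic-data module generates stained tiles, segmentation volumes and
    cohort tables with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    RNifti,
    survival,
    ranger,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Survival, Clustering, FeatureExtraction
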