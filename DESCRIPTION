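Package: pcdradiomics
Title: Radiomic Analysis of Nanoparticle Contrast-Enhanced Spectral
    Photon-Counting Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for differentiating tumors by
    lymphocyte burden from nanoparticle contrast-enhanced spectral
    (photon-counting) versus conventional (energy-integrating) micro-CT.
    Provides a synthetic spectral phantom generator, calibration-vial based
    sensitivity-matrix estimation and per-voxel basis-material decomposition
    (iodine / photoelectric / Compton), seeded region-growing tumor
    segmentation, semantic iodine metrics, a 3D agnostic radiomic feature bank
    (shape, first order and five texture families on the original image and
    all one-level wavelet sub-bands), univariate Wilcoxon screening with
    Benjamini-Hochberg control, minimum-redundancy-maximum-relevance feature
    ranking, and a stratified Monte Carlo repeated cross-validation harness
    with ridge-logistic classification, pooled ROC curves and paired
    signed-rank model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
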