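Package: ctvbm
Title: Voxel-Based Morphometry from Brain CT and MR Head Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end voxel-based morphometry (VBM) pipeline that works
    from X-ray CT head volumes as well as T1-weighted MR: CT brain extraction
    by Hounsfield windowing and morphology, prior-weighted Gaussian-mixture
    tissue segmentation fitted by EM, affine plus low-frequency cosine-basis
    spatial normalization to a gray-matter template, isotropic Gaussian
    smoothing, and a mass-univariate two-group general linear model with
    cluster-extent thresholding and cluster-level false discovery rate
    control (random-field and permutation modes). Includes a synthetic head
    phantom generator (paired CT/MR renderings with known tissue labels and
    injectable regional atrophy) used as the test substrate.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
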