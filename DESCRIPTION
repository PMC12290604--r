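Package: vasodyn
Title: Laminar VASO and BOLD Hemodynamic Response Analysis with a
    Layered-Cortex Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar cerebral-blood-volume (VASO) and
    BOLD functional MRI acquired with a symmetric slice-selective
    slab-inversion (SS-SI) VASO sequence: framewise-displacement quality
    control, run averaging, 4-fold temporal upsampling, BOLD-contamination
    correction by dynamic division, temporal SNR and 1/CV T1-weighted maps,
    equivolume cortical depth estimation and layer binning, geodesic disc
    regions of interest, jittered event-related averaging with short/long
    inter-trial-interval stitching, voxelwise general linear models with
    gamma hemodynamic response regressors and discrete-cosine high-pass
    drift terms, and time-to-peak and vessel/gray-matter peak-ratio
    statistics. A generative simulator of interleaved blood-nulled and BOLD
    time series over a layered cortical ribbon with vessel-dominated voxels
    provides ground truth so that every stage is testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
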