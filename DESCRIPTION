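Package: npqcell
Title: Single-Cell Decomposition of Nonphotochemical Quenching from
    Chlorophyll Fluorescence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping nonphotochemical quenching (NPQ) in
    single microalgal cells from pulse-amplitude-modulated chlorophyll
    fluorescence time-lapse data. Provides light-protocol modelling,
    simulation of per-cell maximal-fluorescence (Fm') traces and of
    synthetic fluorescence movies, watershed-based cell segmentation and
    trace extraction, outlier filtering and normalization, sparse
    dictionary learning of elementary trace waveforms, projection of
    dictionary codes into a three-dimensional NPQ trait space (qT, qE,
    qI) via linear discriminant analysis with a biologically anchored
    change of basis, and downstream heterogeneity statistics
    (repeat-distance distributions, coefficients of variation, grid-trace
    maps, and affine trend fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    glmnet,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
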