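Package: vinecanopy
Title: Vineyard Canopy Characterisation from UAV and Satellite Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating vineyard canopy structure from
    multispectral remote sensing. Computes NDVI from fine-resolution
    (UAV-scale) and coarse-resolution (satellite-scale) reflectance rasters,
    segments vine canopy, interpolates continuous vigour surfaces by inverse
    distance weighting, classifies three-level vigour zones by NDVI quintiles,
    extracts per-vine spectral and geometric features over systematic uniform
    random (SUR) sampling designs, and links remote-sensing variables to
    manually measured canopy height, width, leaf wall area (LWA) and tree row
    volume (TRV) through log-linear regression gated on residual normality,
    in both single-point (SPD) and vigour-class-aggregated (AD) modes. A
    synthetic vineyard scene generator provides row-structured ground truth
    and imagery at both resolutions for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml,
    nortest,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
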