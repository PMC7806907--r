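Package: treescope
Title: Object-Based Tree Crown Segmentation, Classification and
    Explanation from UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A machine-vision toolchain for individual tree identification
    and mapping from drone (UAV) RGB orthomosaics and digital surface
    models. Derives a slope model from the DSM, delineates tree crowns by
    multiresolution region-merging segmentation of a colour/elevation/slope
    layer stack, scores segmentations against reference crowns with a
    five-category overlap scheme, extracts grey-level co-occurrence matrix
    (GLCM) texture features for support vector machine classification,
    trains a compact convolutional network on extracted crown images, and
    explains CNN decisions with Grad-CAM, guided backpropagation and
    Guided Grad-CAM attention maps. A seeded synthetic-forest generator
    provides fully reproducible benchmark scenes so the entire pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    png,
    jsonlite,
    yaml,
    e1071,
    pracma,
    tibble,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
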