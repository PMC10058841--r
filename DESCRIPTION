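Package: TreeSpectra
Title: Component Classification of Hyperspectral LiDAR Tree Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies fruit-tree point clouds acquired with hyperspectral
    LiDAR into wood, leaf, ripe-fruit and unripe-fruit components. Provides
    white-reference reflectance calibration, extraction of nine spectral
    feature parameters (band reflectances, red-edge chlorophyll index, NDVI,
    NDRE), preliminary per-point classification with random forest, support
    vector machine or back-propagation neural network, spatial-distance
    label reprogramming that corrects misclassified edge points by
    k-nearest-neighbour majority vote, coordinate-matched accuracy
    evaluation, colored 3D reconstruction export, and a synthetic
    spectral-tree scene generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
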