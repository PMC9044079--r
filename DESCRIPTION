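Package: grain3d
Title: 3D Wheat Grain and Ventral Sulcus Phenotyping from Surface Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for structured-light surface scans of wheat
    grains. Reads merged point clouds of many grains on a stage, removes the
    stage plane by RANSAC, splits the remainder into single grains by
    normal-based region growing, and extracts 28 grain-shape traits plus 4
    ventral-sulcus traits per grain (32 in total): oriented-bounding-box
    length/width/thickness, mesh surface area and enclosed volume, projected
    outlines, roundness and sphericity, and cross-section slice measures
    including groove depth. Includes a cross-validated regression harness
    (linear, Bayesian ridge, k-nearest-neighbour, random forest, gradient
    boosting) for single-grain weight prediction, Taguchi L9 range analysis
    for scan-condition screening, and a synthetic grooved-grain generator
    with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    FNN,
    generics,
    ggplot2,
    interp,
    jsonlite,
    purrr,
    RANN,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
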