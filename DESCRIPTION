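Package: wheattips
Title: Simulated Wheat Seedling Canopies with Automatic Leaf-Tip
    Annotation and Detection Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Procedurally simulates three-dimensional wheat seedling
    canopies from architectural parameters (phyllochron, leaf dimensions,
    inclination, sowing density), renders them to annotated RGB images with
    a z-buffer rasterizer (Lambertian shading, cast shadows, procedural or
    user-supplied textures), and places leaf-tip bounding-box labels
    automatically from the scene geometry. Includes sliding-window tiling
    to training-size subimages, COCO/CSV dataset interchange including
    label re-attachment to externally translated images, a classical
    vegetation-index/skeleton baseline detector, IoU-matched detection and
    counting metrics (precision, recall, MAE, RMSE, R squared) with
    per-development-stage reporting, a feature-space domain-gap measure
    with t-SNE embedding, and drivers for realism-factor and
    spatial-resolution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    lhs,
    Rtsne,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
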