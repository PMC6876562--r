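Package: olivecloud
Title: Point-Cloud Phenotyping of Young Olive Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic extraction of architectural traits of young olive trees
    from UAV photogrammetric point clouds. Implements an object-based pipeline:
    digital terrain model generation by chessboard tiling with a lowest-points
    rule, per-point height normalization, height-threshold tree point
    classification, individual crown delineation on a 0.1 m occupancy grid with
    seed-based splitting for hedgerow (super-high-density) plantings,
    voxel-based crown volume estimation, and per-tree trait tables (height,
    crown width/length, projected area, volume). Includes the field-validation
    statistics used in orchard phenotyping trials (counting accuracy, bias,
    R-squared, RMSE, nRMSE, cone/circle field formulas) and a synthetic-orchard
    generator with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
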