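Package: shallotvision
Title: Machine-Vision Yield Monitoring and Size Grading of Shallots on a
    Harvester Conveyor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and sizes individual shallot bulbs in RGB images of a
    harvester conveyor belt using HSV color thresholding followed by
    marker-controlled watershed segmentation of the Euclidean distance
    transform. Pixel diameters are converted to millimetres through a
    reference-object calibration (pixels-per-mm ratio estimated with a
    Circle Hough Transform on a ball of known diameter), bulbs are graded
    into small/medium/large market classes, and per-frame counts are
    geotagged from NMEA 0183 position logs into CSV/GeoJSON yield maps.
    Includes the full evaluation battery for such a monitor (greedy
    centroid matching, precision/recall, RMSE, two-sample
    Kolmogorov-Smirnov tests with asymptotic p-values) and a seeded
    synthetic conveyor-scene generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
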