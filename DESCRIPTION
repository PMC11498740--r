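Package: orbimetry
Title: Landmark Triangulation and Measurement on a Sphere of Oriented Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for metric analysis of specimens photographed from a
    calibrated sphere of viewpoints, as produced by automated multi-view
    digitization rigs. Implements a pinhole camera model with Brown-Conrady
    lens distortion, pixel back-projection, least-squares triangulation of
    2D landmarks observed in two or more oriented images, metric scale
    calibration from a token of known physical size, inter-landmark
    distance measurement, nearest-view retrieval for pseudo-3D navigation,
    a versioned JSON project format with calibration importers and CSV
    landmark export for geometric morphometrics, replicate-measurement
    comparison statistics (percent difference to a reference technique,
    inter-operator difference, range dispersion, repeatability summaries),
    and a synthetic-scene generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
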