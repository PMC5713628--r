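Package: phenokit
Title: Modular Image Analysis Toolkit for High-Throughput Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for measuring plant shoot phenotypes from raster
    images. Provides illumination normalization (white balance, median and
    Gaussian smoothing), automatic global and adaptive thresholding (triangle,
    Otsu, mean, Gaussian), size-marker area reporting, grid-based multi-plant
    detection and image splitting, distance-transform watershed segmentation
    for organ (leaf) counting, acute-region and axis pseudo-landmark
    morphometrics, a trainable two-class and multiclass naive Bayes pixel
    classifier based on HSV kernel density estimates, and a parallel per-image
    pipeline runner with filename-metadata parsing and SQLite result
    aggregation. A seeded synthetic-scene generator produces rosette plants,
    trays, and class-colored images with known ground truth so every component
    is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jpeg,
    DBI,
    RSQLite,
    jsonlite,
    parallel,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
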