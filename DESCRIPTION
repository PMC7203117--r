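Package: trackatlas
Title: Trajectory-Image Atlases and Consensus Classification of Cell Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts time-lapse cell trajectories into binary trajectory
    images (visual atlases) referenced to biologically meaningful points,
    extracts high-dimensional descriptors from them with a fixed
    convolutional backbone, and classifies drug-treated versus untreated
    conditions with a linear support vector machine under video-exclusive
    two-fold testing, aggregating per-track decisions by majority voting at
    neighborhood, cluster, and video level.  Includes a probabilistic
    frame-to-frame tracker (windowed drift/volatility Gaussian displacement
    likelihood solved as an optimal assignment problem), a circular Hough
    cell detector, a 28-descriptor kinematic baseline, and a synthetic
    motility simulator so the whole pipeline is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
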