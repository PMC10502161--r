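Package: insect3d
Title: Dual-Camera 3D Insect Tracking and Movement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional insect positions and trajectories
    from two orthogonally mounted cameras observing a plant. Provides
    landmark-ratio camera calibration (millimetres per pixel), conversion
    between per-camera pixel coordinates and pot-centred world coordinates,
    YOLO-style detection label file input/output, a naive blob detector,
    normalized colour-histogram appearance features with
    histogram-intersection matching, nearest-neighbour frame-to-frame
    association with greedy fragment re-identification and false-track
    pruning, movement statistics (total travelled distance and windowed
    speed profiles), point-cloud export and trajectory plotting, and a
    seeded scene simulator that generates ground-truth trajectories and
    noisy dual-camera detection streams for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lattice,
    yaml,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
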