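Package: fallwatch
Title: Visual Fall Detection with Moving Cast Shadow Removal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An indoor video-surveillance pipeline for detecting unexpected
    falls of a monitored person from an RGB (optionally RGB-D) camera.
    Foreground segmentation combines a per-pixel Gaussian mixture background
    model with weighted differencing of consecutive frames; moving cast
    shadows are removed with a two-stage spectral test (an HSV value-ratio /
    hue / saturation mask followed by a normalized-rgb chromaticity mask);
    objects are tracked with a fixed-gain alpha-beta-gamma filter; and a
    cascaded two-stage detector classifies falls from the bounding-box
    aspect ratio, the normalized vertical velocity of the silhouette
    centroid, and the variation of its mean depth. A synthetic indoor-scene
    generator with per-pixel ground truth (background / actor / shadow)
    and scripted activities (walking, standing, crouching, four fall
    directions) makes the whole stack testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
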