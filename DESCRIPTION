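Package: hessianblob
Title: Hessian Blob Particle Detection for Atomic Force Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic, parameter-stable detection of particles in atomic
    force microscopy (AFM) height images. Particle centers are found as
    scale-space maxima of the scale-normalized determinant of the Hessian,
    boundaries are delineated as closed zero-crossing contours of Gaussian
    curvature at the selected scale, and both are refined to subpixel
    precision. Includes strength-based culling with automatic (Otsu or
    k-means) thresholds, particle measurement (area, perimeter, heights),
    and a synthetic ground-truth image generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
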