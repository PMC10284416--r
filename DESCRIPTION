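Package: levelseg
Title: Level-Set Image Segmentation Without Re-Initialization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variational level-set segmentation of 2-D grayscale images using
    the distance-regularized ("no re-initialization") active-contour model: a
    penalty energy keeps the level-set function close to a signed distance
    function while geodesic length and weighted area terms drive the zero
    level set onto object boundaries. The edge indicator that gates the
    evolution can be computed from a Gaussian-smoothed or a bilateral-filtered
    image; the bilateral variant preserves object edges while suppressing
    noise. Includes synthetic noisy-scene fixtures with known ground truth,
    sub-pixel zero-contour extraction, contour accuracy metrics (mean
    distance, Hausdorff), region-cropped PSNR evaluation with staged timing,
    and a command-line interface for running and comparing both variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
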