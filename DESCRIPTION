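Package: gpfseg
Title: Level-Set Segmentation with Gradient-Vector-Interaction Fields and
    Kernel-Density Shape Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variational level-set segmentation of 2D grayscale images
    driven by a global gradient-vector-interaction image feature (the
    geometric potential field) combined with a nonparametric
    kernel-density shape prior over signed distance functions.  Includes
    FFT-based computation of the interaction field with a brute-force
    reference path, centroid-aligned shape distances and shape gradient
    flows, narrow-band explicit evolution with reinitialization, synthetic
    annulus phantom generators for end-to-end testing, and
    foreground/background accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
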