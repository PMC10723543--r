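Package: retwave
Title: Contrastive Pre-Training on Retinal Waves and Neural Manifold Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how spontaneous retinal activity can shape visual
    representations. Simulates movies of propagating retinal waves with an
    excitable-medium model, segments them into wave events, and builds shuffled
    control datasets. Pre-trains a small convolutional encoder with a temporal
    contrastive (SimCLR-style) objective in which consecutive frames of a wave
    event are positive pairs, evaluates frozen-encoder linear readouts on
    classification, spatial-translation and color-change image tasks, and
    characterizes representation geometry: mean-field manifold capacity,
    dimension and radius, empirical simulation capacity from linear
    separability of random dichotomies, participation ratio, manifold center
    correlations, and explained-variance dimensionality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    tiff,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
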