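Package: curvelm
Title: Curvelet Features and Optimized Extreme Learning Machines for
    Fundus-Based Glaucoma Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a complete toolkit for binary glaucoma screening from
    128x128 fundus regions of interest: a wrapping-based fast discrete
    curvelet transform (forward, inverse, tight frame) with per-wedge
    statistical feature extraction; principal component analysis with
    normalized-cumulative-variance component selection followed by a Fisher
    discriminant stage; an extreme learning machine whose output weights are
    the minimum-norm least-squares (Moore-Penrose) solution; a pelican
    optimization metaheuristic (plain and modified prey-rule variants) used
    to tune the hidden-layer weights and biases; stratified repeated k-fold
    cross-validation with accuracy, sensitivity and specificity reporting;
    and exact analytic gradient-based saliency maps (vanilla gradients,
    integrated gradients, SmoothGrad) over the input image. A synthetic
    fundus generator with controllable cup-to-disc ratio makes every stage
    testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
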