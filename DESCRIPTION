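Package: eyecenter
Title: Hybrid Eye-Center Localization with Isophote Voting and Fern-Cascade Face Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes iris/eye centers in face images by combining two
    complementary estimators. An unsupervised isophote-curvature voting
    scheme accumulates curvedness-weighted votes into center maps at five
    Gaussian scales and extracts separation-constrained maximum isocenters
    as candidate eye centers. A trainable two-level cascade of random-fern
    regressors with shape-indexed pixel-difference features aligns a full
    facial landmark shape, from which each eye center is reconstructed as
    an affine-invariant linear combination of neighboring landmarks; the
    candidate nearest that reconstruction is the final estimate. Includes
    seeded synthetic eye-patch and schematic-face generators for training
    and evaluation without external datasets, a normalized-error evaluation
    metric with worst/best/average accuracy curves, frame-to-frame tracking
    that seeds the face box from the previous frame's landmarks, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
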