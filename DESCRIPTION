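Package: brainfuse
Title: Brain-Age Prediction from Structural MRI Fused with Blood Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brain-age regression from gray-matter density volumes with a 3D
    residual convolutional network, deep transfer learning (frozen
    convolutional weights), and multimodal compact bilinear (MCB) fusion of
    the 256-dimensional image embedding with a 14-parameter blood panel.
    Includes Grad-CAM attention extraction with atlas-based region-importance
    scoring, permutation comparison of paired prediction errors, bootstrap
    mediation analysis with bias-corrected confidence intervals, PCA of the
    stitched feature matrix, and a seeded synthetic-cohort generator
    (age-dependent regional atrophy plus correlated blood biomarkers) so the
    whole pipeline is testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    digest,
    e1071,
    glmnet,
    randomForest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
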