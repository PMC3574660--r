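Package: meshreg
Title: Topology-Preserving Nonrigid Image Registration with Spring-Analogy
    Mesh Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intensity-based nonrigid (deformable) registration of 2-D and 3-D
    scalar images. The displacement field is estimated by alternating a
    renormalized optical-flow (demons-style) similarity force with a
    regularization step that treats the pixel grid as a triangular mesh of
    linear springs whose stiffness is inversely proportional to edge length,
    so that the recovered deformation preserves topology (no folds, crossings
    or tears; everywhere-positive Jacobian determinant). Includes a
    multiresolution pyramid driver with cross-correlation stopping rule,
    post-hoc Jacobian correction and template updating; evaluation utilities
    (Jacobian diagnostics, label propagation, Dice/kappa overlap); a synthetic
    phantom and ground-truth warp generator; NIfTI input/output; and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
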