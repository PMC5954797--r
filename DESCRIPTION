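Package: printqa
Title: Quality Assurance Toolkit for Medical 3D Printing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quality assurance for CT-based anatomic modeling and
    3D printing. Provides parametric generators for two printable QA phantoms
    (a line-pair resolution block and a multi-object geometric accuracy
    phantom), a simulator of CT acquisition effects on triangle meshes
    (partial-volume voxelization, reconstruction-kernel blur, slice-thickness
    averaging, image noise), threshold segmentation and iso-surface
    extraction, morphological wrapping and volume-compensated smoothing with
    measurable detail loss, rigid iterative-closest-point registration with
    point-by-point signed surface-distance validation, line-pair gap and
    resolvable-frequency analysis, longitudinal QA logging against
    operational limits, and a synthetic print-error generator (offsets,
    warps, rigid misplacement, loss of thin features) for closed-loop
    testing without a physical printer. Meshes are exchanged as STL, annotated
    surfaces as PLY, and volumes as NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
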