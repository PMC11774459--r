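Package: vesselmark
Title: Vessel Bifurcation Landmark Refinement for Registration Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and validating vessel-bifurcation landmark
    pairs on contrast-enhanced CT, as used for deformable image registration
    (DIR) quality assurance. Implements an iterative sphere-growing algorithm
    that refines type-1 bifurcation landmarks to the widest point of the
    vessel junction, with a multiscale Hessian vesselness / region-growing
    fallback for difficult cases; a digital phantom engine (synthetic vessel
    trees plus exactly invertible rotation-scale-sinusoid deformations) for
    estimating landmark accuracy; and target registration error (TRE)
    evaluation utilities including landmark projection through deformation
    vector fields, outlier handling and paired testing. Volumes are read and
    written as NIfTI with full affine geometry; landmarks as CSV/JSON in
    world millimetres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
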