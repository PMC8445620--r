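Package: laminarkit
Title: Equivolumetric Laminar Profiling, Cytoarchitectural Gradients and
    Warp Evaluation on Cortical Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for intracortical analysis of laminar image volumes on
    cortical surface meshes: construction of equivolumetric intracortical
    surfaces between pial and white boundaries, sampling and smoothing of
    staining-intensity depth profiles, moment-based cytoarchitectural
    features, diffusion-map-embedding gradients of profile similarity,
    evaluation of volumetric nonlinear registrations (Jacobian determinant,
    label Dice overlap, anatomical-fiducial misregistration), geodesic
    iso-to-allocortical axis modelling with ribbon volumetrisation and
    axis-binned functional-connectivity profiling, and deterministic
    synthetic fixtures (folded cortical sheets, laminar volumes,
    displacement fields, axis-graded BOLD) so every pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
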