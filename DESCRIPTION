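Package: clemdock
Title: Landmark-Based 3D Correlation, Registration and Docking for
    Correlative Light-Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeting a region of interest imaged by intravital
    two-photon microscopy inside a serially sectioned, resin-embedded
    electron-microscopy block. Endogenous anatomical landmarks (vessel
    bifurcations, collagen-fiber cross-points, near-infrared branding
    surface marks) are paired across the two volumes, a spatial transform
    (rigid, similarity, affine or Bookstein thin-plate spline) is fitted to
    the paired landmark sets, and the region of interest is projected
    ("docked") into the block frame with a leave-one-out accuracy estimate
    and serial-section depth guidance. A synthetic skin-tissue generator
    with a parametric embedding-deformation model provides ground truth for
    validating every step without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
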