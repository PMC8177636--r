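Package: nuctraction
Title: Inverse Traction-Force Inference from Nuclear Outline Deformation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the minimum-free-energy deformation field between
    successive 2-D outlines of an elastically deforming cell nucleus and
    computes the surface traction-force field that produced it, under two
    limiting mechanical models: a homogeneous incompressible elastic solid
    and a thin (Love-Kirchhoff) elastic shell. Boundary correspondence is
    found by Metropolis simulated annealing of the deformation free energy.
    Includes outline segmentation from grayscale images (Otsu threshold,
    crack-boundary tracing), radial-spoke ensemble averaging of outlines,
    front/rear-weighted translation removal, synthetic shape and
    deformation-pair generators with known ground truth, and an end-to-end
    pipeline producing arclength-parametrised traction profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
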