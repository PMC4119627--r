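Package: scalpexp
Title: Finite-Element Simulation of Scalp Soft-Tissue Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the large-deformation mechanics of scalp soft-tissue
    expansion with a total-Lagrangian finite-element model: linear tetrahedral
    elements, a Fung-type exponential hyperelastic material with a volumetric
    penalty, Newton-Raphson equilibrium iterations with the consistent tangent
    stiffness, and a growing virtual ellipsoid expander that applies follower
    pressure to the contacted scalp surface. Includes mesh readers and writers
    for Gmsh, legacy VTK and a minimal Abaqus input dialect, synthetic
    spherical-shell fixture meshes, Delaunay-based surface-area estimation from
    sampled surface points, per-step area and volume reports, and the
    shrinkage-corrected expander-sizing arithmetic used in surgical flap
    planning.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    interp,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
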