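Package: fetoflow
Title: Fetal Great-Artery Geometry, Flow and Wall Shear Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational hemodynamics pipeline for the great
    arteries of the fetal mouse. Generates seeded synthetic episcopic-image-like
    voxel stacks and Doppler-like velocity data for a parametric great-artery
    tree; performs speckle filtering, lumen segmentation, surface extraction
    and centerline morphometry; assembles hematocrit-dependent blood
    properties and Murray's-law flow boundary conditions; solves steady
    low-Reynolds incompressible Newtonian flow with a reduced-order Poiseuille
    network solver and structured tube-grid solvers; and post-processes wall
    shear stress and rate, unwrapped shear maps, centerline Reynolds and
    Womersley numbers, normalized helicity, and per-vessel developmental
    trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
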