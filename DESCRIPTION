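Package: scaffem
Title: Lattice Scaffold Implant Design and Finite-Element Evaluation for
    Segmental Bone Defects
Version: 0.1.0
Authors@R:
    person("scaffem", "developers", email = "scaffem@example.org",
           role = c("aut", "cre"))
Description: Tools for designing porous titanium lattice implants that bridge
    large segmental bone defects and for evaluating them mechanically and
    mechanobiologically. Generates a trabecular-like rhombic-dodecahedral strut
    network with an external quadrilateral grid shell and gradient strut
    diameters, assembles a linear-elastic finite-element model (Timoshenko
    beams for struts, hexahedral voxels for bone and graft, grounded springs
    for masticatory muscles), sweeps the graft material over three healing
    stages (granulation tissue, immature bone, mature bone), computes binned
    stress/strain frequency statistics against a yield-stress criterion and
    the Frost mechanostat strain window, and iteratively resizes overstressed
    struts until both criteria are met. Includes seeded synthetic
    mandible-segment fixtures and STL import/export so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
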