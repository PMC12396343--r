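Package: anisoprint
Title: Anisotropic Voxel Mechanics and Conformal Toolpath Planning for
    Direct Ink Writing of Tissue Simulants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form prediction and inverse design of the directional
    elastic anisotropy of orthogonal print-line infill lattices, together
    with a conformal toolpath planner for nonplanar substrates: STL
    ingestion and height-minimizing reorientation, bottom-template
    conformal layering, fiber-orientation-driven print-line generation
    with cross-unit continuity, a recursive depth-first-search optimizer
    that minimizes the number of distinct extrusion paths,
    inclination-dependent nozzle-height and volumetric flow compensation,
    machine-command output, and arithmetic planning of embedded
    fluid-filled capsule payloads.  Includes seeded synthetic-data
    generators (meshes, orientation fields, stress-strain curves,
    spanning-width tables) so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
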