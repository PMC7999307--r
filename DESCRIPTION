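Package: bonereduce
Title: Virtual Bone Fracture Reduction by Constrained ICP and Mesh Zippering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic virtual reduction of comminuted bone fractures from
    segmented triangle meshes. Labels fragment surfaces as intact (cortical) or
    fracture (cancellous-exposed) from per-vertex Hounsfield intensities, aligns
    fragment fracture surfaces to a base bone with a constrained,
    confidence-weighted, hierarchical iterative closest point (ICP) algorithm
    (point-to-point and point-to-plane variants with boundary-pair exclusion and
    degeneracy diagnostics), and integrates the aligned meshes into one
    consensus surface by redundant-triangle removal, boundary-wall clipping and
    small-triangle cleanup. Includes a procedural phantom generator that
    simulates fractures with known ground-truth displacements and synthetic CT
    intensities, evaluation metrics (fracture-line distance profiles, degree of
    alignment, mean-distance classification), STL/PLY input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
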