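Package: nfindex
Title: Face-Based Topological Indices for Planar Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for computing valency-based topological indices on planar
    molecular graphs of polycyclic compounds. Builds hydrogen-suppressed
    carbon skeletons of fused-ring benzenoid hydrocarbons from hexagon-cell
    specifications or 2D MOL/SDF files, enumerates the faces of the planar
    embedding via its rotation system, and computes the neighborhood face
    index (NFI), the face index, the Randic (vertex-connectivity) index and
    the edge-connectivity index. Ships a 21-compound benzenoid reference
    dataset with pi-electron energies and boiling points, ordinary
    least-squares machinery for structure-property regressions on those
    descriptors, and parametric generators with closed-form NFI formulas for
    graphene, H-naphthalenic and C4C8 nanosheet families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
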