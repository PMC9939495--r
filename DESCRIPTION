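Package: aneugraph
Title: Semantic Vessel Graphs, Centerlines and Morphometry for
    Intracranial Aneurysm Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing class-labelled surface meshes of
    intracranial vasculature. From a triangle mesh segmented into inlet,
    aneurysm, bifurcation and vessel regions the package builds a semantic
    vessel graph with refined anatomical roles (aneurysm bifurcation,
    parent vessel, aneurysm vessel) and vessel levels, detects inlets and
    outlets on open or closed meshes, computes maximal-inscribed-sphere
    centerlines with radius, curvature and torsion profiles, cuts and
    extrudes vessel ends perpendicular to the local axis for flow
    extensions, and extracts morphological indices (aspect ratio, size
    ratio, bottleneck factor, parent-vessel diameter with bifurcation
    exclusion, per-level vessel statistics). A synthetic generator of
    watertight tubular vessel trees with aneurysm sacs and complete ground
    truth makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    RANN,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
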