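Package: plaquefe
Title: Inverse Finite-Element Characterization of Heterogeneous Arterial Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers multi-parameter constitutive properties of intra-plaque
    tissue classes (healthy wall, mixed, fibrous, lipid, calcium) from two
    geometric states of a pressurized diseased vessel. Provides a synthetic
    labeled-vessel generator, small-strain and finite-strain (Yeoh
    hyperelastic) finite-element solvers with luminal pressure loading, an
    interface-matching objective built from tissue-tissue and tissue-surface
    node-set intersections, a two-stage NSGA-II plus SQP optimization, and
    verification harnesses for parameter recovery under displacement noise and
    pressure perturbation. Labeled meshes are exchanged as VTK unstructured
    grids and Gmsh MSH 4.1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
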