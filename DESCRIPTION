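Package: conspocket
Title: Protein-Ligand Binding-Site Prediction from Surface Geometry and
    Residue Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ligand binding pockets on protein structures by
    combining geometric cleft detection with evolutionary conservation.
    Surface atoms are identified by per-atom solvent-accessible surface
    area (Shrake-Rupley), clefts are the surface atoms left after removing
    an expanded convex-hull shell, candidate atoms are filtered by
    ConSurf-style residue conservation grades, clustered by single linkage
    into pockets, and ranked by conservation score or pocket volume.
    Includes the PocketPicker 4 Angstrom hit criterion, TOP-N benchmarking,
    a two-factor parameter sweep, a deterministic synthetic-fixture
    generator with planted pockets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
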