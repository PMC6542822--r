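Package: capsidgeom
Title: Geometry and Symmetry Analysis of Prolate Bacteriophage Capsids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of tailed-bacteriophage head
    assemblies such as phi29: construction of prolate Caspar-Klug capsid
    lattices (triangulation number T, elongation number Q) with capsomer and
    head-fiber site enumeration and protein stoichiometry; cyclic point-group
    operators, symmetry expansion and head-tail orientation-mismatch
    statistics for the 12-fold connector inside the 5-fold capsid vertex;
    least-squares (Kabsch) superposition, per-range C-alpha RMSD and
    centre-of-gravity displacement in a common capsid frame; rotational
    steric clash scanning with MolProbity-style clashscores; density-grid
    operations including model rasterization, Fourier shell correlation,
    map-model correlation, magnification (pixel-size) calibration and local
    n-fold density averaging; interface geometry (radial diameter profiles,
    salt bridges, buried surface area); and seeded synthetic-structure
    generators with planted ground truth for validating every analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
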