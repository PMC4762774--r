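Package: xpqspr
Title: Quantum-Topological XP Indices and QSPR Models for Polybrominated Xanthones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the eigenvalue-based quantum-topological molecular
    descriptors XP1 and XP2 from spatial distance matrices, equilibrium
    electronegativities and atomic branching degrees, for xanthone and its
    135 polybrominated congeners or for arbitrary molecules supplied as XYZ
    or MOL/SDF files.  Provides the congener enumerator, an idealized planar
    geometry generator, group and equilibrium electronegativity calculators,
    and a two-descriptor multiple-linear-regression toolkit with fit
    statistics, leave-one-out cross-validation (PRESS, cross-validated
    correlation) and relative-property transforms, together with the curated
    congener thermodynamic data table used to exercise the models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
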