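Package: flexff
Title: Automated Flexibility Force-Field Parameterization for Periodic and Molecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates and types the internal coordinates (bond stretches,
    Urey-Bradley stretches, angle bends, proper dihedral torsions) of a
    periodic crystal or molecule from its bond graph, prunes redundant
    coupled dihedral types while preserving symmetry equivalency, classifies
    each dihedral type as rotatable, hindered, non-rotatable or linear,
    generates rigid torsion scans, projects scan energies onto an orthogonal
    seven-mode torsion basis with smart mode selection, and fits all
    flexibility force constants simultaneously by bounded, weighted LASSO
    regression against reference atom-in-material forces and torsion-scan
    energies, with full training and validation statistics. A built-in
    synthetic-reference oracle emulates the quantum-chemistry reference data
    (optimized geometry, finite-displacement sets, pseudo-molecular-dynamics
    sampling, torsion scans) so the whole pipeline runs end-to-end at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
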