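Package: billmech
Title: Biomechanics of Cavity-Excavating Bird Bills
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Comparative excavation biomechanics of two-layered bird bills.
    Generates parametric maxilla geometries (outer keratinous rhamphotheca
    over an inner bony core), meshes them with linear tetrahedra, solves
    small-strain linear elasticity under impact and torsion loading with a
    built-in finite-element solver, evaluates closed-form elliptical-beam
    performance metrics (Euler critical buckling stress, maximum torsional
    shear stress), and analyses species-level performance with phylogenetic
    comparative statistics (Spearman correlations, phylogenetic generalized
    least squares under Pagel's lambda, Wilcoxon signed-rank tests and
    phylogenetic paired t-tests) on simulated clades with Brownian-motion
    trait evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
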