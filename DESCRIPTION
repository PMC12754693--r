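Package: footmorph
Title: Multi-Bone Statistical Shape Modeling of Foot and Ankle Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical shape modeling of the 14-bone foot and
    ankle complex. Generates parametric synthetic weight-bearing cohorts
    with exactly planted radiographic angles (Meary's angle, hindfoot
    alignment angle, calcaneal inclination), reads and writes triangulated
    surface meshes (PLY/STL/OBJ), performs iterative-closest-point rigid
    alignment and generalized Procrustes analysis of multi-bone
    correspondence particle systems, fits principal-component shape models
    with parallel-analysis mode retention, runs per-mode group statistics
    (ANOVA/Tukey, Welch/Games-Howell, effect sizes) and per-particle
    Hotelling T2 significance maps separating alignment from shape
    differences, and computationally derives radiographic angles from 3D
    bone meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
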