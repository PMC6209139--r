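Package: posturegm
Title: Geometric Morphometrics of Animal Posture from Dorsal-Outline Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics toolkit for quantifying
    animal posture from two-dimensional photographs of the dorsal outline.
    Reads tpsDig-style landmark files, performs generalized Procrustes
    superimposition, slides semilandmarks along the outline by thin-plate-spline
    bending-energy minimization, removes the nuisance rotation of an articulated
    subset (the neck) by fixing a three-point angle, and summarizes shape with
    principal components and deformation grids. A mixed-model ANOVA harness with
    individual as a random factor compares how well alternative landmark /
    semilandmark schemes discriminate populations (e.g. riding schools), and a
    synthetic-data generator produces articulated dorsal outlines with known
    group structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
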