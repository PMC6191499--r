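Package: florasym
Title: Landmark-Based Geometric Morphometrics of Floral Symmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing two-dimensional landmark shape variation
    into symmetric and asymmetric components for any finite symmetry group
    (bilateral C1v, disymmetric C2v, rotational Cn, rotational-plus-reflection
    Cnv). Reads and writes TPS and NTS landmark files, applies symmetry-group
    relabelling maps to build expanded datasets of transformed relabelled
    copies, performs Generalised Procrustes Analysis with rotation-only
    superimposition and tangent-space projection, classifies principal
    components of the expanded dataset into symmetry categories, detects and
    rotates equal-eigenvalue PC pairs, and provides one-way nested Procrustes
    ANOVA for measurement error together with a permutation test for
    allometry. Includes a synthetic-data generator for symmetric flower
    templates with isotropic landmark noise and nested imaging and digitising
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
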