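Package: jawstrain
Title: Finite-Element Analysis of Periodontal Ligament Effects on Mandibular Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-strain linear elastic finite-element pipeline for
    studying how the periodontal ligament (PDL) shapes strain regimes in
    the mandible during simulated unilateral chewing. Provides tetrahedral
    mesh handling (Abaqus-INP subset, native JSON, legacy VTK export), a
    CT grayscale-to-density-to-elasticity material calibration with binned
    heterogeneous cortical assignment, PDL material variants, muscle-force
    loading from physiological cross-sectional area and EMG scaling, a
    sparse direct static solver on four-node tetrahedra, principal and
    anatomical-plane shear strain analysis, strain-gauge-frame readouts,
    element-level differential strain maps between model variants, boxplot
    whisker validation against in-vivo strain samples, and a parametric
    mandible-phantom generator so the whole pipeline runs on synthetic
    data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
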