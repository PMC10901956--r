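Package: MechanoCT
Title: Cross-Section Morphometry and Mechanostat Simulation of Cortical
    Bone Adaptation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying local cortical bone adaptation from
    binarised micro-CT cross-section images of the mouse tibia loading
    model, and for simulating that adaptation with beam-theory mechanostat
    models. The image side extracts periosteal and endosteal contours from
    binary slices, registers them on the principal bending axis, and
    measures local surface movement and cortical thickness changes between
    loaded and contralateral control limbs. The simulation side evolves
    the two cortical surfaces under an eccentric axial load using the
    generalised flexure formula and piecewise-linear mechanostat rate laws,
    and calibrates formation rates by staged full-factorial grid search
    against measured adaptation fields. A synthetic cohort generator with
    known ground truth supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    mgcv,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics
RoxygenNote: 7.3.3
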