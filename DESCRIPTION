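Package: osteofe
Title: Subject-Specific CT-to-Finite-Element Modelling of Plated Femur Fractures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-specific finite-element models of locking-plate
    osteosynthesis from CT-like Hounsfield-unit volumes. Provides a voxel
    material database with node-wise nearest-voxel modulus mapping that
    survives geometry manipulation (fracture gap, screw holes), a synthetic
    phantom-femur generator, Hounsfield-unit to Young's-modulus material
    laws, a structured tetrahedral assembly mesher, a linear-static
    heterogeneous elasticity solver on linear tetrahedra, and the mechanical
    demand metrics used to assess fracture fixation: interfragmentary
    motion, averaged peak plate von Mises stress, and strain-threshold bone
    volume (EqSV) across staged callus healing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
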