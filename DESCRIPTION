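Package: pfasim
Title: Pulsed-Field Ablation Simulation in Anisotropic Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of cardiac pulsed-field ablation (PFA)
    on synthetic myocardial tissue scenarios. Builds slab and vein-ostium
    geometries with an embedded two-electrode catheter and parametric fiber
    fields, assembles field-dependent anisotropic conductivity tensors from
    fiber orientation with an electroporation sigmoid, solves the nonlinear
    quasi-static potential problem by Picard iteration on a structured
    hexahedral grid, steps the Pennes bioheat equation under a gated biphasic
    pulse-train protocol with prescribed blood-flow cooling, and computes
    lesion metrics (threshold ablation volume, surface ablation area,
    isosurface extents) together with anisotropic-versus-isotropic
    comparison statistics.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
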