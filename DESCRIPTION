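Package: tumorflow
Title: Interstitial Fluid Flow and Nanodrug Transport in Solid Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finite-element and closed-form radial solvers for steady
    interstitial fluid pressure in a three-region solid tumor (necrotic
    core, viable rim, surrounding healthy tissue) with Starling
    transvascular exchange and lymphatic drainage, plus a transient
    convection-diffusion-reaction solver for nanoparticle transport after
    intratumoral injection. Includes a structured triangular mesh
    generator, parameter presets for vascular normalization levels and
    common nanodrug carriers, scenario runners for parameter sweeps, and
    export of fields and summaries to VTK, CSV and JSON.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
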