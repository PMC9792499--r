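Package: ivdfem
Title: Anisotropic Hyperelastic Finite-Element Modeling of Intervertebral Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for explicit finite-element simulation of intervertebral
    disc (IVD) mechanics on linear tetrahedral meshes. Provides fiber-reinforced
    Mooney-Rivlin constitutive models for the annulus fibrosus and a compressible
    Mooney-Rivlin model for the nucleus pulposus, acoustic-tensor longitudinal
    wave speeds with both a dense direction-maximization and a cheap
    five-direction approximation for adaptive critical time stepping, a
    parametric synthetic spinal-segment mesh generator with circumferential
    +/-30 degree collagen fiber frames, a total-Lagrangian explicit quasi-static
    solver with rigid vertebra constraints and ramped moment loading, field
    statistics (histograms, ECDFs, wave-speed audits), and inverse-FEM
    calibration of annulus parameters from moment-rotation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tibble,
    ggplot2,
    rlang,
    generics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
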