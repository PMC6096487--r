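Package: edgeom
Title: Diffraction Geometry Modelling, Refinement and Diagnostics for
    Continuous-Rotation Electron Diffraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling, simulating, refining and diagnosing the
    diffraction geometry of continuous-rotation electron-diffraction (ED)
    experiments. Provides vectorial beam/detector/goniometer/crystal models,
    Ewald-sphere reflection prediction with closed-form rotation-method
    crossing angles, Timepix quad frame preparation, detector distortion-map
    generation and application, dispersion-threshold spot finding,
    restraint-stabilised Levenberg-Marquardt refinement of static and
    scan-varying (Gaussian-smoothed) beam and crystal models, and
    Jacobian-based diagnostics (per-block corrgrams and condition numbers)
    that quantify why ED geometry refinement is ill-conditioned relative to
    the X-ray case. A built-in simulator generates fully synthetic rotation
    experiments with known ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
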