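Package: rgbmocap
Title: Marker-Based Motion Capture with RGB Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a low-cost marker-based motion-capture
    pipeline from synchronized RGB cameras: a projective (DLT-style)
    camera model with ray-based triangulation, wand calibration of
    multi-camera rigs from a two-marker wand of known length, synthesis
    of annotated training images of virtual spherical markers for
    object-detection models, multi-view marker correspondence search
    with ray-distance gating, Bland-Altman accuracy evaluation and
    reprojection-noise robustness analysis, plus a scene simulator that
    generates ground-truth rigs, gait-like marker trajectories, wand
    sweeps and rendered frames for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
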