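Package: rfopm
Title: Design, Simulation and Validation of Remote-Focusing Oblique Plane Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational toolkit for remote-focusing oblique plane
    light-sheet microscopy (RF-OPM). Provides the closed-form optical design
    calculator for the tilted light-sheet geometry (tilt angle, aperture
    matching, magnification, per-axis field of view, required tunable-lens
    focal range), a model of the synchronization between an electrically
    tunable lens (ETL) and a rolling-shutter CMOS camera, a forward simulator
    rendering raw sheared stacks of synthetic fluorescent bead fields, the
    affine deskew reconstruction that unwarps raw stacks into Cartesian
    volumes, and a bead-based point-spread-function characterization pipeline
    (detection, per-axis Gaussian fits, FWHM-versus-depth profiles, averaged
    bead images). Includes plain-text multi-page TIFF input/output with JSON
    metadata sidecars and a subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
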