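Package: cellshock
Title: State-Equation Analysis of Single-Cell Deformation Under Shock Loading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the projected-area response of single adherent
    cells to sub-millisecond hydraulic shock loading. Provides a synthetic-data
    generator for cell populations, pressure ramps and deformation records
    (optionally rendered as high-speed image stacks with ground-truth masks);
    segmentation and contour morphometrics; a compression/shear deformation
    decoupling; three area-pressure state equations (exponential area-modulus,
    logarithmic-integral, and Tait-like forms) with derivative and
    inflection-point analysis, a two-compartment cytoplasm/nucleus model and
    discrete isobaric-trajectory continuation across loading rates; and an
    inference layer with distributional validation, peak-pressure grouping,
    per-group linear fits, nonlinear state-equation fitting with a parameter
    recovery harness, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    minpack.lm,
    deSolve,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
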