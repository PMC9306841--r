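Package: bluemack
Title: Calibrated Skin-Colour Quantification and Crowding-Stress
    Inference for Atlantic Mackerel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying crowding-stress induced skin colour
    change in Atlantic mackerel (Scomber scombrus) from calibrated
    digital photographs. Implements chart-based colour correction and
    white-background exposure normalisation in linear RGB, CIELAB
    conversion, green-plane stripe masking of the dorsal thumbnail,
    cage-geometry crowding-density estimation, and the variance-
    structured inferential toolkit used to relate skin blueness to
    crowding exposure, plasma physiology and post-mortem time:
    generalised least squares with group-wise variance weights,
    random-intercept linear mixed models, penalized cubic-spline mixed
    models with power-of-mean variance, REML/ML estimation, Wald-F and
    likelihood-ratio tests, and Wilson score intervals. A synthetic-data
    module renders striped dorsal images with known ground-truth colour
    through a distorting camera model and simulates trajectory,
    physiology, mortality and post-mortem cohorts so the full pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    splines,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
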