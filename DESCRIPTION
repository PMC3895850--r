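Package: aortastretch
Title: Quadrant-Resolved Circumferential Wall Stretch of the Ascending
    Aorta from Displacement-Encoded MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for displacement-encoded (DENSE)
    magnetic resonance images of the ascending aortic wall: spline
    delineation of the thin annular wall, certainty-weighted normalized
    averaging of wrapped phase, least-squares (Poisson/DCT) phase
    unwrapping, balanced multi-point displacement decoding, tracking of
    equidistant mid-wall points through the measured displacement field,
    periodic-spline regularized circumferential stretch profiles, and
    quadrant-resolved stretch asymmetry statistics (two-way ANOVA with
    Tukey contrasts, stretch versus cine cross-sectional area change).
    Includes a synthetic phantom generator with analytically known
    deformation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
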