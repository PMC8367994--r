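Package: tonguegait
Title: Tongue Kinematic Gait Analysis for Electromagnetic Articulometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for midsagittal electromagnetic articulometry
    (EMA) recordings of flap-sequence speech: discrete-cosine-transform
    penalized-least-squares smoothing with missing-sample restoration,
    rigid alignment to an idealized occlusal plane, landmark-anchored time
    normalization into 31 Procrustean slices, cumulative path-distance and
    angular-displacement metrics with z-scored combination into tongue-front
    displacement, per speaker and token displacement ranges, a bounded
    windowed critical-fluctuation statistic for short movement series,
    mixed-effects modelling of token duration against displacement range and
    reiterant speech rate, and additive mixed-effects modelling of
    fluctuation over the token time course with first-order autocorrelation
    correction. Includes a deterministic synthetic-cohort generator with
    programmed speaker gait profiles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    lme4,
    lmerTest,
    mgcv,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
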