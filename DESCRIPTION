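Package: ccmorph
Title: Corneal Confocal Microscopy Nerve Fiber Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of the corneal sub-basal nerve plexus from in vivo
    confocal microscopy images. Segments bright curvilinear nerve fiber
    bundles with a Hessian-eigenvalue tubularity filter and an adaptive
    background threshold, extracts a medial-axis skeleton graph, and computes
    the standard morphometric endpoints (nerve fiber density, branch density,
    fiber length, two nerve fiber area variants, and fiber-bundle width
    frequency distributions). Includes the statistical toolkit used in
    small-fiber-neuropathy studies (Mann-Whitney ROC areas with
    Hanley-McNeil standard errors and correlated-AUC comparison,
    accuracy-maximizing cut points, Passing-Bablok method-comparison
    regression, quadratic length-area modelling, minimum detectable change,
    square-root normalization, ANCOVA for baseline-adjusted treatment
    effects), plus a seeded synthetic plexus phantom and cohort generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
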