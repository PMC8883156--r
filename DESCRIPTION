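Package: matodd
Title: Material Discrimination Analysis with Oddity Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for large-scale visual material
    discrimination experiments. Provides the Ward reflectance model with
    its perceptual gloss reparameterization (contrast gloss c and
    distinctness-of-image gloss d), procedural generation of bumpy-sphere
    stimulus images spanning six material dimensions (gloss contrast,
    gloss distinctness, translucency, gold-plastic, silver-glass and
    glossy-painted), Monte-Carlo estimation of oddity-task sensitivity
    (d-prime) with finite-trial correction, compressed color texture
    statistics from a complex steerable pyramid, and regression of
    discrimination sensitivity on per-feature image distances with a
    fixed-support lasso.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
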