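Package: smcdeform
Title: Smooth Muscle Cell Deformation After Short-Duration Heating Balloon Dilatation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and measures the deformation of arterial smooth muscle
    cells (SMCs) after short-duration heating balloon dilatation. Provides a
    one-dimensional transient heat-conduction solver for the balloon film and
    vessel wall with an apparent (temperature-band-dependent) heat capacity
    reflecting collagen thermal denaturation, the depth of wall tissue heated
    above the 60 degree Celsius denaturation threshold, area-conserving
    annulus dilation mechanics with local stretch fields, a synthetic
    histology phantom generator with known ground truth, nuclei ellipse
    morphometry via second-order image moments, and the study's rate
    statistics (SMC deformation rate, arterial dilatation rates, vessel-wall
    transformation rate, media area-conservation checks) with an end-to-end
    reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
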