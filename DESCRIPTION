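Package: straylight
Title: Simulation of Ocular Straylight and Subjective Straylight Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating the effect of intraocular straylight on
    vision tests. Implements the CIE general disability-glare formula as a
    two-dimensional glare-spread-function kernel, convolution-based veiling
    of arbitrary grayscale images, a simulated wide-field straylight meter
    with an image-based straylight index (SI), calibration and inversion of
    the glare-angle/SI relationship, generation of Sloan-style visual acuity
    optotype charts degraded by prescribed SI levels, the subjective
    straylight function (SSF) and subjective straylight index (SSI) computed
    from per-chart tolerance responses, a simulated observer and synthetic
    cohort generator, and the accompanying population statistics (SSI
    histogram with Gaussian peak fit, Pearson correlations with wavefront
    aberration terms and photostress recovery times).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    png,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
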