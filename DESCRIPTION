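Package: powdertex
Title: Fractal and Texture Image Analysis for Powder Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative image analysis of dispersed-powder micrographs for
    particle-size quality control. Computes box-counting (Minkowski-Bouligand)
    fractal dimension as a function of the binarization threshold and of the
    box size, gray-level co-occurrence matrices with Haralick texture
    descriptors (angular second moment, contrast, correlation, entropy) in
    four directions, and autoscaled principal component analysis of particle
    size distributions and fractal-dimension signatures to discriminate
    in-specification from out-of-specification batches. Includes a synthetic
    transmitted-light image generator (lognormal particle-size mixtures,
    uniform or clustered placement) so the whole workflow is testable without
    proprietary microscope images, and a batch pipeline with a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
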