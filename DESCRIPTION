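Package: icootseg
Title: Multilevel Image Thresholding with an Improved Coot Optimization
    Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multilevel Otsu thresholding of 8-bit grayscale images driven
    by the coot-bird swarm optimizer and an improved variant that adds
    Levy-flight perturbation and quasi-opposition-based learning. Provides
    the population optimizer over box-bounded continuous spaces, the
    between-class-variance objective with an exhaustive-search oracle,
    segmentation of images into intensity classes, reference
    implementations of the PSNR, SSIM and FSIM image-quality metrics
    (including a log-Gabor phase-congruency map), synthetic multimodal
    test-image generators, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
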