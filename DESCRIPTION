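Package: livermetsim
Title: Virtual CT Imaging Trials of Fractal Liver Metastases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A virtual imaging trial pipeline for studying how CT
    reconstruction kernels affect the recovery of liver-metastasis
    characteristics. Generates random fractal lesion shapes with nested
    heterogeneity inserts and known ground-truth labels (internal
    heterogeneity, edge sharpness, edge fractal dimension), measures edge
    fractal dimension by box counting, simulates 2D fan-beam CT scans of
    synthetic liver backgrounds with lesions superimposed in the sinogram
    domain, reconstructs with standard (smooth) and high-frequency
    (edge-preserving) filtered back projection kernels, and trains compact
    residual convolutional regressors to recover the ground-truth
    characteristics from reconstructed image patches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
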