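Package: boclahe
Title: Bayesian-Optimized CLAHE for Low-Contrast Grayscale Radiographs
Version: 0.1.0
Authors@R:
    person("boclahe", "maintainers", email = "boclahe@example.org",
           role = c("aut", "cre"))
Description: Per-image automatic selection of CLAHE (contrast limited
    adaptive histogram equalization) hyperparameters by Gaussian-process
    Bayesian optimization of a combined SSIM/BRISQUE image-quality
    objective, applied within a lung-region mask. Includes a from-scratch
    CLAHE implementation (tiling, histogram clipping with excess
    redistribution, bilinear blending of tile mappings, masked
    application), full-reference SSIM, a no-reference BRISQUE-style
    feature pipeline with an asymmetric generalized Gaussian fitter, a
    Matern-kernel Gaussian-process surrogate with UCB/EI acquisition, a
    deterministic synthetic chest-phantom generator with ground-truth
    lung masks for offline testing, and evaluation utilities (Dice,
    Jaccard, classification metrics, AUC, one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
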