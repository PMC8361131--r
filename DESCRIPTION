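Package: metalsim
Title: Simulated Psychophysics of Metallicity Perception from Low-Level
    Image Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how low-level image statistics can support
    judgements of metallicity, the visual quality of looking metallic.
    Generates a two-axis synthetic stimulus space in which Gaussian blur
    stands in for decreasing metal smoothness and a smooth random
    pixel-displacement ("local disarray") warp stands in for coating
    bumpiness; computes radially averaged power spectra, steerable-pyramid
    level activations and a family of global contrast estimators; enumerates
    and simulates maximum-likelihood difference-scaling (MLDS) and conjoint
    measurement (MLCM) experiments with noisy model observers; fits the
    independent, additive and saturated conjoint decision models by probit
    maximum likelihood with nested likelihood-ratio tests and bootstrap
    confidence intervals; and fits a two-parameter metallicity model that
    weights fine-scale against coarse-scale pyramid activations.
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
    withr,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
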