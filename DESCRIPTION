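Package: visnorm
Title: Image-Computable Normalization Models of Visual Cortex Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements four image-computable encoding models of fMRI BOLD
    responses in human visual cortex (V1-V3) to band-pass textures: contrast
    energy, untuned divisive normalization, orientation-tuned (surround)
    normalization, and normalization by orientation anisotropy. Includes a
    synthesizer for the band-pass texture families used to probe the models
    (snakes, gratings, noise bars, waves, plaids, circular patterns), an
    oriented contrast-energy pipeline built on a quadrature Gabor filter bank,
    multi-start least-squares fitting with leave-one-out cross-validation and
    a variance-explained metric, and diagnostic experiments (snakes-to-gratings
    response ratio, contrast-slope analysis, center-surround suppression
    simulations, and a parameter-recovery harness on synthetic BOLD data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
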