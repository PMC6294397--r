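Package: classim
Title: Classification-Image Analysis of Noisy-Bar Psychophysics with Model Observers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis machinery for two-alternative forced-choice
    detection and discrimination of a luminance bar embedded in one-dimensional
    Gaussian luminance noise. Generates the noisy-bar stimulus protocol
    (including double-pass blocks), simulates a family of sequential model
    observers (template matcher, energy model with and without divisive gain
    control, MAX uncertainty model, and hybrid two-branch architectures),
    estimates internal noise from double-pass response consistency via a
    two-parameter signal detection theory model, computes first- and
    second-order classification-image descriptors with their expected noise
    floors ("drives"), eigen-decomposes second-order descriptors against a
    decoupled-process null, and summarises tuning with sharpness, linearity,
    separability and efficiency metrics over a contrast-by-SNR condition grid.
    Also simulates the classic threshold-versus-pedestal (dipper) contrast
    discrimination function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
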