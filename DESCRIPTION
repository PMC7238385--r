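Package: pcgmurmur
Title: Segmentation and Classification of Pediatric Heart Murmurs from
    Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for intelligent auscultation of pediatric phonocardiograms:
    wavelet soft-threshold denoising, heart-sound segmentation by discrete
    wavelet decomposition with Hadamard-product recombination and Shannon
    energy enveloping, extraction of time-frequency features from the
    closed-valve (systolic and diastolic) intervals, and screening of
    congenital heart disease murmurs with a Levenberg-Marquardt-trained
    neural network evaluated by leave-one-out jack-knife. Includes a
    synthetic phonocardiogram generator with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
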