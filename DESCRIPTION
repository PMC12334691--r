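Package: pupilflux
Title: Pupillary-Light-Reflex-Driven Retinal Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pupillary-light-reflex (PLR) driven
    retinal ganglion cell activity: pupillometry (ellipse-fit pupil area,
    constriction kinetics, frequency tracking), two-photon calcium trace
    processing (neuropil correction, per-trial dF/F, response quality
    index), noise-correlation axon grouping, functional response
    clustering, binocular modulation and trial-covariance SNR analysis,
    and human detection psychophysics. Includes a forward simulator from
    stimulus protocol through pupil dynamics and retinal illuminance to
    bouton calcium traces and observer key-presses, so every stage is
    testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    mclust,
    tiff
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
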