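Package: stereovol
Title: Design-Based Stereology on Synthetic Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the classical design-based stereology workflow for
    quantifying a neuronal cell layer: Cavalieri point-counting estimation of
    reference volume with a Gundersen-Jensen coefficient of error, physical
    disector estimation of numerical density and total cell number with
    unbiased counting frames, and nucleator estimation of mean somal volume on
    vertical uniform random sections with tissue-shrinkage correction.
    Includes a synthetic 3D phantom generator (cell layers of known volume,
    number and size distribution), a virtual microtome with systematic uniform
    random section sampling, a two-group statistical layer (group means,
    coefficients of variation, Student's t-tests, size-distribution
    comparison), and an end-to-end simulated-study pipeline so every estimator
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
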