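Package: lcmicro
Title: Automated 3D Lamina Cribrosa Microarchitecture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated analysis of the three-dimensional microarchitecture of
    the lamina cribrosa (LC) in optical coherence tomography (OCT) volumes:
    local-threshold beam/pore segmentation after noise removal, sphere-fitting
    (maximal inscribed sphere) thickness morphometry, per-C-mode-slice pore
    area and aspect-ratio measurement, and repeatability statistics based on a
    nested random-effects measurement-error model. Includes a synthetic LC
    phantom generator with known ground-truth microstructure, speckle noise,
    vessel shadows and simulated repeat scans, so the whole pipeline can be
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
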