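Package: sagloc
Title: Probabilistic Template-Matching Model of Sagittal-Plane Sound Localization
Version: 0.1.0
Authors@R: person("sagloc", "maintainers", email = "sagloc@example.org", role = c("aut", "cre"))
Description: Implements a probabilistic template-matching model of human
    sound localization in sagittal planes. Directional transfer functions
    (DTFs) are reduced to an auditory internal representation by a
    gammatone filterbank; incoming sounds are compared to an internal
    template set via the standard deviation of inter-spectral differences,
    and a Gaussian similarity mapping with a listener-specific uncertainty
    parameter U yields probability mass vectors over polar response
    angles. Provides quadrant-error and local polar RMS-error metrics,
    grid-search calibration of U against response data, and a factor
    analysis that permutes DTF sets (acoustic factor) and uncertainties
    (non-acoustic factor) across a listener group to compare their
    contributions to localization performance. Includes a synthetic
    virtual-listener generator, response simulation, CSV and SOFA I/O,
    and an end-to-end study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
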