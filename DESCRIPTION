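Package: mitospot
Title: Automated Proliferation Quantification and Hot-Spot Selection for
    PHH3/MART1 Dual-Stained Histology
Version: 0.1.0
Authors@R:
    person("Mitospot", "Developers", email = "mitospot@example.org",
           role = c("aut", "cre"))
Description: Fully automated quantification of tumor-cell proliferation in
    PHH3/MART1 dual-stained slide images: color deconvolution of
    hematoxylin, DAB and alkaline-phosphatase red, pixel classification,
    detection of PHH3/MART1-positive cells with chromatin fusion and
    post-processing gates, MART1-verified tumor area, circle-overlap
    heat-map hot-spot selection in a fixed 1-mm^2 square, and
    MART1-adjusted proliferation indices.  Ships a calibrated synthetic
    slide-phantom generator with exhaustive ground truth, and the
    method-comparison statistics (Bland-Altman agreement, detection
    contingency tables, hot-spot overlap categories, diagnostic
    performance) used to evaluate automated against manual reading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    digest,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
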