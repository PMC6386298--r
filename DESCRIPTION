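Package: ccfv
Title: Choriocapillaris Flow-Void Analysis Around Geographic Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choriocapillaris (CC) flow impairment around
    geographic atrophy (GA) on en-face optical coherence tomography
    angiography (OCTA). Implements structural shadow compensation and
    Phansalkar local-threshold binarization of the CC angiogram,
    distance-map ring regions (para- and peri-atrophy, two 500 um rings)
    around the GA border, flow-void percentages (FV_OUT, FV_500, FV_1000)
    and their difference (dFV), the square-root-transformed yearly growth
    rate of GA, and the cohort statistics linking flow voids to growth
    (Pearson correlation, two-way random-effects ICC, and generalized
    estimating equations with exchangeable working correlation and robust
    standard errors). Ships a synthetic en-face OCTA generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
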