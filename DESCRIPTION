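Package: octaquant
Title: Widefield OCT-Angiography Vessel Density Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies en-face optical coherence tomography angiography
    (OCTA) slabs of the superficial and deep retinal capillary plexuses and
    the choriocapillaris over a widefield six-region grid. Implements dual
    global/local binarization (Huang fuzzy-entropy and local-median
    thresholding) for the retinal plexuses, Phansalkar local thresholding
    with small-particle removal for the choriocapillaris, exclusion of the
    footprint of large superficial vessels from the deeper slabs,
    topology-preserving skeletonization, and per-region perfusion density
    and vessel length density. Ships a synthetic angiogram generator with
    exact polyline ground truth and two-group cohort simulation, plus the
    statistical layer of a case-control study design: Shapiro-Wilk-gated
    two-sample comparisons with controls-minus-cases differences, Pearson
    correlation tables, power and sample-size calculation, and an
    age-by-group interaction check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
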