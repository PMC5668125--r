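Package: morphoqc
Title: Morphology-Based Quality Grading of Human iPSC Phase-Contrast Images
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grades the culture quality of human induced pluripotent stem
    cell (hiPSC) colonies from phase-contrast micrographs using three
    biologically interpretable morphological features: the number of
    prominent nucleoli (dark oval blobs, 3-6 micrometres), the crack area
    rate (bright curvilinear intercellular gaps, detected with an oriented
    Gabor filter bank), and the differentiating-nuclei area rate (dark oval
    nuclei around 10 micrometres, segmented by a seeded iterative graph
    cut). Per-region feature vectors are classified into poor / moderate /
    good with a radial-basis-function support vector machine tuned by grid
    search under stratified cross-validation. Includes a synthetic
    phase-contrast scene generator with exact ground truth, multi-rater
    label aggregation, and the evaluation machinery (per-class precision,
    recall, F-measure, per-stratum breakdowns, detector-truth agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    EBImage,
    tiff,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Software, Visualization
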