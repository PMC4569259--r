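Package: aqoce
Title: Convex-Envelope Based Automated Quantification of Multi-Voxel 1H-MRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated frequency-domain quantification of in vivo proton
    magnetic resonance spectroscopy (1H-MRS) chemical-shift-imaging (CSI)
    data.  Implements a five-step pipeline: exponential apodization and
    Fourier transformation of the raw free induction decay, lower-convex-
    envelope baseline fitting by an incremental linear-time scan,
    NAA-anchored chemical-shift bias correction, sectional baseline removal
    over four overlapping ppm ranges combined by a pointwise minimum, and
    window-maximum metabolite peak detection.  Computes the metabolite
    ratios (Cho/NAA, Cho/Cr, Lip-Lac/Cr) used for glioma grading, and the
    accompanying cohort statistics: independent-sample t tests,
    Kruskal-Wallis tests with Dunn-style pairwise rank comparisons, a
    three-ratio logistic combination model, and empirical ROC analysis with
    Youden cut-off selection.  Includes a reader/writer for a Siemens-style
    .rda CSI raw format and seeded generators for synthetic spectra, CSI
    grids and ratio cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    pROC,
    jsonlite
Config/testthat/edition: 3
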