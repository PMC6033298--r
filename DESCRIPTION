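Package: histostep
Title: Stepwise Fine-Tuning and Low-Cost Medium-Level Datasets for
    Histopathology Patch Classification
Version: 0.1.0
Authors@R:
    person("histostep", "developers", email = "histostep@example.org",
           role = c("aut", "cre"))
Description: Tools for gastric histopathology patch classification with a
    two-stage ("stepwise") fine-tuning scheme and two cheaply produced
    intermediate ("medium-level") training datasets: a tissue-wise builder
    (background/epithelium/stroma from coarse annotation masks) and a fully
    automatic cell-wise builder that measures nuclei by H&E color
    deconvolution, Phansalkar adaptive local thresholding, watershed
    splitting and border-following contour tracing, then pseudo-labels
    patches by K-means on (total nuclear area, nucleus count). Includes a
    Beer-Lambert synthetic H&E patch generator with ground truth, a small
    CNN training backend, ROC/AUC evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
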