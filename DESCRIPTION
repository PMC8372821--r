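Package: radlat
Title: Radiomic Laterality Analysis of Temporal Lobe Epilepsy from FLAIR MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for lateralizing temporal lobe epilepsy from
    FLAIR-like MR volumes and anatomical parcellations. Resamples volumes to an
    isotropic grid, normalizes intensity with the white-stripe method, assembles
    hippocampal and extrahippocampal temporal regions of interest, extracts a
    1,618-dimensional radiomic feature vector per region (first-order, shape,
    gray-level co-occurrence and run-length texture, and undecimated wavelet
    sub-band features), selects discriminative features by pooled t-tests with
    Benjamini-Hochberg false-discovery control, fits an elastic-net penalized
    logistic laterality model with cross-validated hyperparameters, and
    evaluates it with ROC/AUC, Youden thresholds and bootstrap confidence
    intervals. Includes a seedable phantom-cohort simulator so the full
    pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
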