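Package: mpradiomics
Title: Multiparametric Prostate MRI Radiomics and Gleason-Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for multiparametric prostate MRI.
    Simulates multiparametric phantom cohorts (diffusion-kurtosis DWI, multi-echo
    T2 relaxometry, T2-weighted volumes with intensity drift and Rician noise),
    fits monoexponential and kurtosis diffusion models and two-parameter T2
    relaxometry voxel-wise with multi-start optimization, standardizes T2-weighted
    intensities by decile-landmark histogram alignment, extracts a 7105-feature
    multi-method texture bank (GLCM, minimum-bounding-box GLCM, local binary
    patterns, Gabor filter banks, Haar wavelet planes, Hu and Zernike moments,
    histograms of oriented gradients, Sobel gradients, and first-order statistics),
    and classifies lesions into low versus high Gleason-score groups with
    leave-pair-out cross-validated regularized logistic regression using
    AUC-filter feature selection and win-score ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    minpack.lm,
    data.table,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
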