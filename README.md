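# mpradiomics

Radiomics analysis of multiparametric prostate MRI (mpMRI) in R: from raw
signal decays to a cross-validated classifier of lesion aggressiveness.

Prostate cancer lesions are graded histopathologically by Gleason score;
separating indolent (Gleason 3+3, "low") from aggressive (>3+3, "high")
lesions non-invasively is a central goal of quantitative prostate MRI.
`mpradiomics` implements a complete pipeline for that task, aimed at
researchers in quantitative MRI and radiomics methodology:

* **Signal models.** Voxel-wise least-squares fitting of the
  monoexponential DWI model *S(b) = S₀ exp(−b·ADCₘ)*, the diffusion
  kurtosis model *S(b) = S₀ exp(−b·ADCₖ + ⅙ b²ADCₖ²K)*, and two-parameter
  T2 relaxometry *S(TE) = S₀ exp(−TE/T₂)*, each multistarted on fixed
  parameter grids (ADCₘ 0.1–3.0 µm²/ms step 0.01; ADCₖ 0.01–3.0 step 0.1;
  K 0.0001–4.0 step 0.2; T2 starts 0–300 ms step 50, constrained to
  [1, 300] ms) with quasi-Newton / Levenberg–Marquardt refinement.
* **T2w standardization.** Decile-landmark (Nyúl-style) histogram
  alignment of T2-weighted intensities inside the prostate mask, removing
  per-patient intensity drift.
* **Texture bank.** Exactly 1281 features per DWI-resolution map
  (ADCₘ, ADCₖ, K) and 1631 per T2w/T2 image — 7105 in total — from
  sliding-window GLCM, lesion-bounding-box GLCM, rotation-invariant
  uniform LBP, Gabor filter banks, Haar wavelet detail planes, Hu and
  Zernike moments, HOG, Sobel gradients, and 18 first-order statistics.
* **Classifier.** Leave-pair-out cross-validation (LPOCV) around L1/L2
  regularized logistic regression with per-round top-1% AUC feature
  filtering and inner stratified 10-fold hyperparameter selection over
  ω ∈ {0.001, 0.01, 0.1, 1, 10}; lesions are scored by number of
  pairwise wins and the win-score ROC AUC is reported with a DeLong-type
  95% CI.
* **Synthetic phantoms.** A seeded generator of multiparametric phantom
  cohorts (kurtosis-decay DWI, multi-echo T2 series, drifting T2w, Rician
  noise, class-dependent textured parameter fields) so the whole pipeline
  is testable without clinical data.

The methods vignette (`vignettes/mpmri-radiomics.Rmd`) documents every
model, parameter and numerical convention in detail.

## Worked example

```r
library(mpradiomics)

report <- run_full_pipeline(run_config(
  n_patients = 4, seed = 17, image_types = "ADCk",
  penalty = "l1", grid = 1, fraction = "all",
  contrast = 2, lesion_counts = c(2, 2, 2, 2), low_fraction = 0.5))
report
```

```
pipeline report [config 2cd25166]
cohort: 4 patients, 8 lesions (4 low / 4 high)

univariate best features:
 image_type                    best_texture best_texture_auc     best_statistical best_statistical_auc
       ADCk ADCk:glcm(d=1):w3:contrast_mean                1 ADCk:stats():w0:mean                    1

LPOCV models:
 image_types n_features n_selected     auc    ci_low ci_high
        ADCk       1281       1281 0.96875 0.8821294       1

final model features: ADCk:stats():w0:mean, ADCk:stats():w0:sd, ADCk:stats():w0:range, ADCk:stats():w0:min, ADCk:stats():w0:max ...
```

Eight phantom lesions are simulated at doubled class contrast and the full
1281-feature ADCₖ bank is extracted per lesion. Several features separate
the classes perfectly in-sample (univariate flipped AUC 1); the
leave-pair-out estimate is more honest — the classifier ranks 96.9% of
low/high pairs correctly (cross-validated AUC 0.969, 95% CI 0.88–1.0).
The univariate table lists each image type's best texture and best
first-order feature, and the final model reports the features selected on
the full cohort.

Fitting a single voxel's noisy decay (SNR 50 at b = 0):

```r
p <- acquisition_protocol()
set.seed(1)
curve <- simulate_dwi_signal(list(S0 = 500, ADCk = 0.9, K = 1.2), p, noise_sigma = 10)
fit_kurtosis_dwi(curve)$params
#> $S0      496
#> $ADCk    0.877
#> $K       1.19
```

A thin command-line front end over the same functions is included at
`inst/cli/mpradiomics.R` with subcommands `simulate`, `fit`,
`standardize`, `extract`, `classify`, and `all`.

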