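---
title: "Multiparametric prostate MRI radiomics: models, features, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric prostate MRI radiomics: models, features, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpradiomics)
```

`mpradiomics` implements an end-to-end radiomics analysis of multiparametric
prostate MRI (mpMRI): voxel-wise signal-model fitting of diffusion-weighted
imaging (DWI) and T2 relaxometry, histogram standardization of T2-weighted
(T2w) intensities, a 7105-feature texture bank over five image types, and a
leave-pair-out cross-validated (LPOCV) logistic-regression classifier of
lesion Gleason-score group (low, 3+3, labeled -1, versus high, >3+3,
labeled +1). Because real mpMRI with histopathological ground truth cannot
ship with a package, a synthetic phantom module generates cohorts with the
statistical structure the analysis assumes, making every stage testable.

This vignette records the scientific and numerical choices behind each
stage: the models and their assumptions, the parameters that matter and
their defaults, what the phantom does and does not emulate, and the known
limitations.

## Signal models

DWI decay is modeled two ways. The monoexponential model is

$$S(b) = S_0\, e^{-b\,\mathrm{ADC_m}}$$

and the kurtosis model adds a quadratic term capturing non-Gaussian
diffusion:

$$S(b) = S_0\, \exp\!\left(-b\,\mathrm{ADC_k} + \tfrac{1}{6} b^2 \mathrm{ADC_k}^2 K\right).$$

T2 relaxometry uses the two-parameter monoexponential
$S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2}$.

Units follow the field convention: $b$ in s/mm^2^, ADC in um^2^/ms, so the
exponent is $b \cdot \mathrm{ADC} \cdot 10^{-3}$ (with $b = 2000$ and
ADC $= 1$, the monoexponential exponent is $-2$). $K$ is dimensionless,
TE and $T_2$ are in ms. The default acquisition protocol has 12 b values
(0--2000 s/mm^2^) with b-dependent numbers of signal averages
(2,2,2,2,2,2,2,2,2,3,4,4) and five echo times (20--100 ms).

### Fitting

All models are fit by least squares **in signal space** -- no log
linearization anywhere, since log transforms distort the noise at low
signal. To avoid local minima the fits are multistarted on fixed grids:
ADC~m~ starts on 0.1--3.0 um^2^/ms in steps of 0.01; (ADC~k~, K) starts on
0.01--3.0 (step 0.1) by 0.0001--4.0 (step 0.2); T2 starts at 0--300 ms in
steps of 50 ms with the fitted value constrained to [1, 300] ms. The grid
asymmetry (fine for the one-parameter decay, coarse for the two-parameter
one) is intentional and kept as such.

Numerical choices:

* $S_0$ enters the residual linearly, so every grid start is scored with
  the closed-form profiled $S_0 = \sum s e / \sum e^2$; the `n_refine`
  (default 10) best starts are then polished with bounded quasi-Newton
  (L-BFGS-B, objective tolerance near machine precision), and for T2 with
  Levenberg--Marquardt. This keeps the multistart contract (the returned
  solution is the lowest-RSS one over the start grid) at a fraction of the
  cost of polishing all ~600 starts. Tests verify the fitted objective
  never loses to an exhaustive brute-force grid oracle.
* The DWI fits end with a Levenberg--Marquardt polish of the best
  candidate: at extreme (ADC~k~, K) the least-squares valley is narrow and
  curved enough that quasi-Newton line searches stall short of the
  minimum, and damped least squares follows it. The kurtosis multistart
  also includes one extra start at the $K = 0$ boundary taken from a fine
  monoexponential scan, which (besides helping convergence) enforces the
  nesting inequality numerically.
* $S_0$ is fit jointly, positive and otherwise unconstrained; ADC and K
  are clamped to their search intervals.
* Signals are clipped to a small epsilon before fitting so that noisy
  zero-signal voxels cannot produce degenerate objectives; an all-zero
  curve is an error, not a silent fit.
* The kurtosis model nests the monoexponential one ($K = 0$), so on any
  curve the kurtosis RSS can never exceed the monoexponential RSS; this is
  asserted in the tests.

`fit_volume()` applies a fitter voxel-wise under a mask, writes NaN
sentinels outside, and returns a convergence QC map alongside the
parameter maps.

## T2w standardization

T2w intensities are relative; scanner gain and coil sensitivity produce a
per-patient multiplicative "intensity drift" that texture features would
otherwise learn. The package uses decile-landmark histogram alignment:
each image's in-prostate deciles (p10..p90) are mapped piecewise-linearly
onto a standard scale, with values beyond the outer landmarks extrapolated
linearly from the end segments. Only prostate-mask voxels drive the
landmarks, since background air and fat would distort them.

Two choices deserve note. The outer landmarks are the 1st and 99th
percentiles rather than min/max -- a robust-endpoint variant that keeps
single outlier voxels from stretching the scale. And the standard scale is
the per-landmark mean across the training images rather than a fixed
interval, which keeps standardized intensities in a familiar range; a
fixed range can be supplied where cross-cohort comparability matters. The
map is monotone (rank order inside the mask is preserved) and idempotent
to numerical tolerance; both properties are tested, as is the strict
reduction of cross-patient landmark dispersion on a drifting phantom
cohort.

## The texture bank

Texture analysis is strictly 2D and per transverse slice (through-plane
voxel anisotropy makes 3D neighborhoods physically inhomogeneous). Square
sliding windows with side lengths 3, 5, ..., 15 voxels are used for the
DWI-resolution maps (ADC~m~, ADC~k~, K) and 3, 7, ..., 35 for the
higher-resolution T2w and T2, keeping physical coverage similar. A window
position is valid when the window lies completely inside the lesion; when
no position fits on a slice, the positions maximizing in-window lesion
area are used instead (all ties kept).

Per image type the bank enumerates exactly 1281 (DWI types) or 1631
(T2w/T2) features; over the five types, 7105. The per-method counts are:

| method | per window | DWI total | T2w/T2 total |
|---|---|---|---|
| first-order statistics | lesion-wide | 18 | 18 |
| GLCM (sliding) | 12 per distance | 324 | 420 |
| MBB-GLCM | 12 per distance, 4 distances | 48 | 48 |
| LBP | 10 histogram bins | 70 | 90 |
| Gabor | 5 freq x 3 sigma x 4 stats | 420 | 540 |
| Haar | 4 levels x 3 planes x 2 stats | 168 | 216 |
| Hu moments | 7 | 49 | 63 |
| Zernike moments | 25 | 175 | 225 |
| HOG | 1 | 7 | 9 |
| Sobel | lesion-wide, 2 | 2 | 2 |

GLCM distances are 1--4 voxels, except that a window only admits distances
up to its own side length (so the 3-window uses distances 1--3); this is
the unique rule consistent with the totals above. A distance with no
admissible pixel pairs yields all-zero features by convention. Gray-level
co-occurrence uses 32 uniform quantization levels over a fixed per-type
intensity range; the defaults anchor each parametric map to its fitting
bounds (ADC 0--3 um^2^/ms, K 0--4, T2 1--300 ms) and T2w to
[0, top standard-scale landmark], since fixed ranges are what make GLCM
features comparable across lesions. Six Haralick features (contrast,
dissimilarity, homogeneity, energy, correlation, angular second moment)
are summarized as mean and range over the four bidirectional orientations
(0/45/90/135 degrees). The minimum-bounding-box (MBB) variant computes the
same 12 values per distance over each slice's lesion bounding box while
masking out non-lesion voxels, then averages over slices.

Other method conventions, each of which had to be pinned down:

* **LBP**: 8 neighbors bilinearly interpolated on a circle at the maximum
  radius the window allows ((w-1)/2, so the code is evaluated at the
  window center), `>=` comparison against the center, uniform patterns
  grouped rotation-invariantly by their number of ones, all non-uniform
  patterns pooled in a tenth bin; the lesion-wise feature is the pooled
  pattern frequency histogram over all valid positions.
* **Gabor**: frequencies 0.1--0.5 cycles/voxel in steps of 0.1, circular
  Gaussian envelopes sigma = 1, 2, 3, complex responses summed over the
  four orientations for orientation robustness; per window, mean of the
  real part, variance of the real part, mean absolute real part, and mean
  magnitude. The real-part statistics are exactly invariant under
  90-degree image rotation; the magnitude of the complex orientation sum
  is only approximately so (conjugate terms), which is why the rotation
  tests assert the real-part statistics.
* **Haar**: four decomposition levels of the orthonormal 2D Haar
  transform on the slice (edge-replicated to a multiple of 16), detail
  planes LH/HL/HH upscaled back by nearest neighbor, windowed mean
  absolute value and standard deviation.
* **Hu moments**: log absolute values of the seven invariants, with
  magnitudes under 1e-30 floored so vanishing invariants stay bounded.
* **Zernike moments**: magnitudes of the complex moments up to degree 8
  (25 (n, m) pairs in lexicographic order) over the disk inscribed in the
  window; magnitudes are rotation invariant, which the tests verify
  exactly on 90-degree grid rotations.
* **HOG**: one cell per window, 8 unsigned orientation bins,
  magnitude-weighted votes; the histogram is L2-normalized and summarized
  by its maximum bin (a scalar concentration measure chosen because the
  bank needs one value per window size, not an 8-vector); per lesion, the
  mean over windows.
* **Sobel**: fixed 3x3 kernel, lesion-wide median of the gradient
  magnitude with edge voxels included, and with them excluded via a
  one-voxel 4-connected erosion (falling back to the inclusive median if
  erosion empties the mask).

Windowed GLCM/Gabor/Haar/Hu/Zernike values are aggregated to one value per
lesion by the median over all valid positions pooled across slices; a
per-slice-median-then-mean mode is also provided, since descriptions of
slice averaging versus median summarization are often ambiguous and the
two differ on asymmetric lesions. Both modes are unit-tested against hand
computations; pooled median is the default.

The windowed GLCM path is internally batched: five of the six Haralick
features are linear functionals of the co-occurrence counts and are
evaluated with summed-area tables over per-pair value maps, with only the
angular second moment requiring per-position histograms. The batched path
is tested for exact agreement with the single-patch reference
implementation.

## The phantom cohort

The generator emulates exactly the structure the downstream analysis
relies on: per-patient ellipsoidal prostate masks; 1--3 disjoint
ellipsoidal lesions with multiplicity probabilities 29:28:5 (matching a
62-patient cohort with 100 lesions); a configurable cohort class ratio
defaulting to 20% low / 80% high; class-dependent (ADC~k~, K, T2, T2w)
Gaussian-random-field parameter maps with class-specific means, variances
and correlation lengths (low-grade tissue: higher ADC, lower K, smoother;
high-grade: lower ADC, higher K, rougher -- the direction reported for
prostate cancer, with magnitudes as configuration, not claims); 4D DWI and
T2-mapping series synthesized voxel-wise from the signal models with
Rician noise (the magnitude-MRI noise distribution), averaging as many
independent draws per b value as the protocol's NSA column specifies; and
a T2w volume multiplied by a smooth patient-specific drift field of
configurable relative amplitude (default 0.3), which is what the
standardization stage exists to remove.

Default phantom grid sizes are 32x32x6 (DWI and T2 map) and 48x48x8
(T2w), with noise sigmas of about 1% of the S0 fields -- values chosen
to give clearly visible but not overwhelming noise; reported phantom SNR
cannot be anchored to any acquisition, so it is a package default, stated
here once. All randomness flows from a single integer seed through derived
per-patient seeds; equal seeds give identical cohorts.

What the phantom does **not** emulate: anatomically realistic prostate and
lesion shapes, inter-modality misregistration, k-space/EPI artifacts,
coil-profile bias beyond the smooth multiplicative drift, and partial
volume effects. Passing tests on the phantom therefore demonstrate the
pipeline's statistical and numerical correctness -- not that any specific
AUC would be attained on clinical data.

## Classification

Features are z-scored and classified with L1- or L2-regularized logistic
regression (glmnet's coordinate descent, which yields exact zero
coefficients under L1). Validation is nested: an outer leave-pair-out CV
-- every unordered pair of lesions held out once -- around an inner
stratified 10-fold CV that picks the regularization hyperparameter from
{0.001, 0.01, 0.1, 1, 10} by mean held-out-fold AUC. The grid values are
interpreted as inverse regularization strengths (the convention of the
mainstream ML implementation of this model); internally the coordinate
descent penalty is lambda = 1/(n omega). Inner-CV ties resolve to the
largest omega (weakest penalty). Fold counts shrink automatically when the
minority class is smaller than the fold count, and folds that would leave
a single-class training or held-out set are dropped rather than producing
silent NaNs.

Within each round, the top 1% of features by training-set AUC are kept
(ties at the boundary break by ascending column index, making selection
deterministic); the AUC filter flips inversely correlated features via
max(a, 1-a). Each round's model compares the held-out pair: the winner's
score increments by the Heaviside of the prediction difference, with
H(0) = 0.5 so exact ties split the pair evenly. A lesion's final score is
its number of wins (0 to n-1); every pair contributes exactly one win, so
the scores always sum to n(n-1)/2. The score-versus-label ROC gives the
cross-validated AUC; its 95% CI comes from a DeLong-type
influence-function variance of the placement values, clipped to [0, 1].
This estimator is documented, not asserted to match any particular
package's small-sample behavior.

Two normalization modes exist because the common practice of z-scoring
before cross-validation leaks held-out information into the training
statistics: the default re-normalizes per round using training rows only;
a `global` mode reproduces the pre-CV variant for fidelity with existing
analyses. Outer-loop hygiene -- the held-out pair never influencing
selection, normalization, or hyperparameter choice -- is asserted by a
test that corrupts the held-out rows and checks the round's selections are
unchanged.

The permutation-null calibration tests use 40-lesion Gaussian noise tables
(200 replicates, single hyperparameter, no filter): under label
permutation the LPOCV AUC must center at 0.5. The null depends only on
label exchangeability, so noise tables exercise it as well as texture
tables at a small fraction of the cost; signal recovery is tested
separately on a seeded strong-contrast phantom cohort (16 lesions,
contrast multiplier 1.5, ADC~k~ + K features), where the cross-validated
AUC must reach at least 0.9.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances chosen to exercise every code path while staying quick: phantom
cohorts of 4--10 patients (6--16 lesions), full 1281/1631-feature
extraction per lesion on the phantom's ground-truth parameter fields,
LPOCV at n up to 40, and 100--200 permutation replicates. Fitting tests
coarsen the multistart grids where the objective's smoothness makes the
full grids redundant, and verify against brute-force oracles at full grid
resolution.

## Known limitations

* The deposited 100-lesion radiomics table of the original prostate study
  is not redistributable inside the package; the reader for its CSV layout
  and the full reproduction path are implemented and tested structurally,
  and the reproduction test runs whenever the file is placed at
  `inst/extdata/s3_lesion_radiomics.csv`.
* Gabor mean-magnitude features are only approximately invariant under
  image rotation (see above).
* Zernike moments are sampled on the pixel grid: the continuum
  orthogonality identities (e.g. all non-(0,0) moments of a constant patch
  vanish) hold only up to a boundary-discretization residue that grows
  with radial degree and shrinks with window size; the tests quantify this
  rather than assuming the continuum result.
* No Rician noise-floor correction is applied before fitting; at very low
  SNR the ADC and T2 estimates inherit the magnitude bias.
* Feature extraction is 2D by design; lesions spanning a single slice
  contribute fewer window positions, and the maximum-overlap fallback for
  windows larger than the lesion measures partly peri-lesional tissue.
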