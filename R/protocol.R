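#' Acquisition protocol for a multiparametric phantom study
#'
#' Bundles the diffusion weightings, echo times, number-of-signal-average
#' (NSA) counts and per-modality grid geometry that the simulator and the
#' fitting routines share. The defaults reproduce a 12-b-value high-b DWI
#' protocol (b = 0--2000 s/mm^2 with b-dependent NSA) and a 5-echo
#' T2-mapping protocol (TE = 20--100 ms).
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2.
#'   Must be strictly increasing and start at 0.
#' @param nsa Integer vector, number of signal averages per b value
#'   (recycled to `length(b_values)` if scalar).
#' @param echo_times Numeric vector of echo times in ms, strictly
#'   increasing and positive.
#' @param dwi_dim,t2_dim,t2w_dim Integer length-3 grid dimensions
#'   (x, y, slices) of the DWI, T2-mapping and T2-weighted volumes.
#' @param dwi_spacing,t2_spacing,t2w_spacing Numeric length-3 voxel
#'   spacings in mm; all entries must be positive.
#' @return An object of class `acquisition_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' p$b_values
#' @export
acquisition_protocol <- function(b_values = c(0, 100, 300, 500, 700, 900, 1100,
                                              1300, 1500, 1700, 1900, 2000),
                                 nsa = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 3, 4, 4),
                                 echo_times = c(20, 40, 60, 80, 100),
                                 dwi_dim = c(32L, 32L, 6L),
                                 t2_dim = c(32L, 32L, 6L),
                                 t2w_dim = c(48L, 48L, 8L),
                                 dwi_spacing = c(2.5, 2.5, 5.5),
                                 t2_spacing = c(0.9, 0.9, 5.0),
                                 t2w_spacing = c(0.8, 0.8, 2.5)) {
  if (length(b_values) < 2L || b_values[1] != 0 || any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing with first value 0")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be positive and strictly increasing")
  nsa <- as.integer(rep_len(nsa, length(b_values)))
  if (any(nsa < 1L)) stop("nsa must be >= 1")
  for (sp in list(dwi_spacing, t2_spacing, t2w_spacing))
    if (length(sp) != 3L || any(sp <= 0)) stop("voxel spacings must be 3 positive values")
  for (dm in list(dwi_dim, t2_dim, t2w_dim))
    if (length(dm) != 3L || any(dm < 4)) stop("grid dimensions must be 3 values >= 4")
  structure(list(b_values = b_values, nsa = nsa, echo_times = echo_times,
                 dwi_dim = as.integer(dwi_dim), t2_dim = as.integer(t2_dim),
                 t2w_dim = as.integer(t2w_dim),
                 dwi_spacing = dwi_spacing, t2_spacing = t2_spacing,
                 t2w_spacing = t2w_spacing),
            class = "acquisition_protocol")
}

#' Tissue class model for phantom generation
#'
#' Describes the voxel-level parameter distributions and the spatial texture
#' of one tissue class (a Gleason-group lesion class, or the background
#' prostate tissue). Parameter fields are drawn as Gaussian random fields
#' with the stated mean, a standard deviation of
#' `texture_variance_scale * mean`, and an isotropic correlation length.
#'
#' @param label Class label: -1 (low Gleason group, 3+3), +1 (high group,
#'   >3+3), or 0 for background tissue.
#' @param adc_mean,adc_sd Kurtosis-model ADC mean / spatial sd (um^2/ms).
#' @param k_mean,k_sd Kurtosis parameter K mean / sd (dimensionless).
#' @param t2_mean,t2_sd T2 relaxation time mean / sd (ms).
#' @param t2w_mean,t2w_sd T2-weighted intensity mean / sd (a.u.).
#' @param texture_correlation_length Isotropic correlation length of the
#'   parameter fields, in voxels (0 = spatially independent noise).
#' @param texture_variance_scale Field sd as a fraction of the mean.
#' @return An object of class `tissue_class_model`.
#' @export
tissue_class_model <- function(label, adc_mean, adc_sd = 0, k_mean, k_sd = 0,
                               t2_mean, t2_sd = 0, t2w_mean, t2w_sd = 0,
                               texture_correlation_length = 0,
                               texture_variance_scale = 0) {
  if (!label %in% c(-1, 0, 1)) stop("label must be -1, 0 or +1")
  means <- c(adc_mean, k_mean, t2_mean, t2w_mean)
  if (any(means <= 0)) stop("all class means must be positive")
  if (any(c(adc_sd, k_sd, t2_sd, t2w_sd) < 0)) stop("sds must be non-negative")
  if (texture_correlation_length < 0) stop("correlation length must be >= 0")
  if (texture_variance_scale < 0) stop("variance scale must be >= 0")
  structure(list(label = label,
                 adc_mean = adc_mean, adc_sd = adc_sd,
                 k_mean = k_mean, k_sd = k_sd,
                 t2_mean = t2_mean, t2_sd = t2_sd,
                 t2w_mean = t2w_mean, t2w_sd = t2w_sd,
                 texture_correlation_length = texture_correlation_length,
                 texture_variance_scale = texture_variance_scale),
            class = "tissue_class_model")
}

#' Default tissue class models
#'
#' Low-grade lesions have high ADC, low kurtosis and smoother texture;
#' high-grade lesions have low ADC, high kurtosis and rougher texture
#' (the contrast direction reported for prostate cancer); the background
#' model stands for benign prostate tissue. Magnitudes are configuration,
#' not biological claims.
#'
#' @param contrast Multiplier (>= 0) on the low/high class separation;
#'   1 = default contrast, 0 = identical classes.
#' @return Named list with elements `low`, `high`, `background`.
#' @export
default_class_models <- function(contrast = 1) {
  mid <- list(adc = 1.30, k = 0.95, t2 = 105, t2w = 420)
  d <- list(adc = 0.35, k = 0.30, t2 = 18, t2w = 70) # half-separation at contrast 1
  list(
    low = tissue_class_model(-1,
      adc_mean = mid$adc + contrast * d$adc, adc_sd = 0.10,
      k_mean = max(mid$k - contrast * d$k, 0.05), k_sd = 0.08,
      t2_mean = mid$t2 + contrast * d$t2, t2_sd = 8,
      t2w_mean = mid$t2w + contrast * d$t2w, t2w_sd = 35,
      texture_correlation_length = 2.0, texture_variance_scale = 0.08),
    high = tissue_class_model(+1,
      adc_mean = max(mid$adc - contrast * d$adc, 0.2), adc_sd = 0.12,
      k_mean = mid$k + contrast * d$k, k_sd = 0.10,
      t2_mean = max(mid$t2 - contrast * d$t2, 40), t2_sd = 9,
      t2w_mean = max(mid$t2w - contrast * d$t2w, 120), t2w_sd = 45,
      texture_correlation_length = 0.8, texture_variance_scale = 0.16),
    background = tissue_class_model(0,
      adc_mean = 1.75, adc_sd = 0.12, k_mean = 0.55, k_sd = 0.07,
      t2_mean = 130, t2_sd = 10, t2w_mean = 520, t2w_sd = 40,
      texture_correlation_length = 1.5, texture_variance_scale = 0.07)
  )
}
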