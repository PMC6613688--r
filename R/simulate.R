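#' Noise-free diffusion-kurtosis signal
#'
#' Evaluates `S(b) = S0 * exp(-b*ADCk/1000 + (1/6) * (b*ADCk/1000)^2 * K)`,
#' the kurtosis representation of the DWI signal decay. With K = 0 it
#' reduces to the monoexponential model `S(b) = S0 * exp(-b*ADCm/1000)`.
#' Units: b in s/mm^2, ADC in um^2/ms, so b*ADC/1000 is dimensionless
#' (b = 2000, ADC = 1 gives exponent -2 at K = 0).
#'
#' @param b Numeric vector of b values (s/mm^2).
#' @param s0 Signal at b = 0 (a.u.), positive.
#' @param adc Apparent diffusion coefficient (um^2/ms), positive.
#' @param k Kurtosis parameter, >= 0 (default 0 = monoexponential).
#' @return Numeric vector of signals, same length as `b`.
#' @export
kurtosis_signal <- function(b, s0, adc, k = 0) {
  bd <- b * adc * 1e-3
  s0 * exp(-bd + bd^2 * k / 6)
}

#' Noise-free monoexponential T2 relaxation signal
#'
#' Evaluates `S(TE) = S0 * exp(-TE/T2)`.
#'
#' @param te Echo times (ms).
#' @param s0 Signal at TE = 0 (a.u.).
#' @param t2 Spin-spin relaxation time (ms).
#' @return Numeric vector of signals.
#' @export
t2_signal <- function(te, s0, t2) s0 * exp(-te / t2)

#' Rician noise
#'
#' Magnitude-MRI noise: the modulus of the true signal perturbed by complex
#' Gaussian noise, `|S + sigma*(X + iY)|` with X, Y standard normal.
#' `sigma = 0` returns the input unchanged.
#'
#' @param s Numeric vector/array of noise-free signal values.
#' @param sigma Noise standard deviation per quadrature channel (>= 0).
#' @return Noisy values, same shape as `s`.
#' @export
rician <- function(s, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  out <- sqrt((s + stats::rnorm(length(s), sd = sigma))^2 +
              stats::rnorm(length(s), sd = sigma)^2)
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

#' Simulate one voxel's DWI decay curve
#'
#' Evaluates the kurtosis model at every b value of the protocol and, if
#' `noise_sigma > 0`, averages `nsa` independent Rician draws per b value
#' (mimicking per-b signal averaging, which gives b-dependent effective SNR).
#'
#' @param params List with elements `S0` (> 0), `ADCk` (> 0, um^2/ms) and
#'   `K` (>= 0).
#' @param protocol An [acquisition_protocol()] (its `b_values` and `nsa`
#'   are used).
#' @param noise_sigma Rician noise sigma (0 = exact signal).
#' @param average_nsa Average the protocol's NSA draws per b value
#'   (default TRUE); FALSE uses a single draw.
#' @return A [decay_curve()] of kind `"dwi"`.
#' @export
simulate_dwi_signal <- function(params, protocol = acquisition_protocol(),
                                noise_sigma = 0, average_nsa = TRUE) {
  if (is.null(params$S0) || params$S0 <= 0) stop("S0 must be positive")
  if (is.null(params$ADCk) || params$ADCk <= 0) stop("ADCk must be positive")
  k <- if (is.null(params$K)) 0 else params$K
  if (k < 0) stop("K must be >= 0")
  s <- kurtosis_signal(protocol$b_values, params$S0, params$ADCk, k)
  if (noise_sigma > 0) {
    nsa <- if (average_nsa) protocol$nsa else rep(1L, length(s))
    s <- vapply(seq_along(s),
                function(i) mean(rician(rep(s[i], nsa[i]), noise_sigma)),
                numeric(1))
  }
  decay_curve(protocol$b_values, s, kind = "dwi")
}

#' Simulate one voxel's multi-echo T2 decay curve
#'
#' @param params List with `S0` (> 0) and `T2` (ms, within [1, 300] to
#'   mirror the fitting constraint).
#' @param echo_times Echo times in ms.
#' @param noise_sigma Rician noise sigma (0 = exact).
#' @return A [decay_curve()] of kind `"t2"`.
#' @export
simulate_t2_signal <- function(params, echo_times = acquisition_protocol()$echo_times,
                               noise_sigma = 0) {
  if (is.null(params$S0) || params$S0 <= 0) stop("S0 must be positive")
  if (is.null(params$T2) || params$T2 < 1 || params$T2 > 300)
    stop("T2 must lie in [1, 300] ms")
  s <- t2_signal(echo_times, params$S0, params$T2)
  if (noise_sigma > 0) s <- rician(s, noise_sigma)
  decay_curve(echo_times, s, kind = "t2")
}

# Separable Gaussian smoothing of an array along every dimension, replicate
# padding at the edges. Used to impose a correlation length on white noise.
.gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  dims <- dim(x)
  smooth_vec <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, kern, sides = 2)[(r + 1):(r + n)]
  }
  if (is.null(dims)) return(as.numeric(smooth_vec(x)))
  for (d in seq_along(dims)) {
    x <- apply(x, setdiff(seq_along(dims), d), smooth_vec)
    # apply() puts the worked dimension first; rotate it back into place
    x <- aperm(x, order(c(d, setdiff(seq_along(dims), d))))
  }
  x
}

#' Render a textured Gaussian random field
#'
#' White Gaussian noise convolved with an isotropic Gaussian kernel of
#' standard deviation `correlation_length` (voxels), renormalized to unit
#' marginal variance, then scaled and shifted so the field has the class
#' mean and a standard deviation of `variance_scale * mean`.
#' `correlation_length = 0` yields spatially independent noise;
#' `variance_scale = 0` yields a constant field.
#'
#' @param shape Integer vector of array dimensions (2D or 3D).
#' @param mean Field mean (positive).
#' @param variance_scale Field sd as a fraction of `mean` (>= 0).
#' @param correlation_length Isotropic correlation length, voxels (>= 0).
#' @param lower Optional lower clamp applied after generation (physical
#'   fields such as ADC or T2 must stay positive).
#' @return Numeric array of dimension `shape`.
#' @export
render_textured_field <- function(shape, mean, variance_scale = 0,
                                  correlation_length = 0, lower = -Inf) {
  if (any(shape < 1)) stop("shape must be positive")
  if (correlation_length < 0) stop("correlation length must be >= 0")
  if (variance_scale == 0) {
    f <- array(mean, dim = shape)
    return(pmax(f, lower))
  }
  z <- array(stats::rnorm(prod(shape)), dim = shape)
  if (correlation_length > 0) {
    z <- .gauss_smooth(z, correlation_length)
    # unit-variance renormalization: smoothing scales the marginal sd by the
    # l2 norm of the separable kernel (exact away from edges)
    r <- max(1L, ceiling(3 * correlation_length))
    kern <- stats::dnorm(-r:r, sd = correlation_length)
    kern <- kern / sum(kern)
    z <- z / sqrt(sum(kern^2))^length(shape)
  }
  pmax(mean + variance_scale * mean * z, lower)
}

# Rasterize an axis-aligned ellipsoid given in normalized [0,1]^3 coordinates
# onto a voxel grid of dimension `dm`.
.ellipsoid_mask <- function(dm, center, radii) {
  cx <- (seq_len(dm[1]) - 0.5) / dm[1]
  cy <- (seq_len(dm[2]) - 0.5) / dm[2]
  cz <- (seq_len(dm[3]) - 0.5) / dm[3]
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  arr <= 1
}

# Draw per-voxel parameter fields for one modality grid: background tissue
# everywhere inside the prostate, lesion-class texture inside each lesion.
.compose_field <- function(dm, prostate, lesion_masks, lesion_models,
                           background, what, lower) {
  g <- function(m) render_textured_field(
    dm, mean = m[[paste0(what, "_mean")]],
    variance_scale = m[[paste0(what, "_sd")]] / m[[paste0(what, "_mean")]],
    correlation_length = m$texture_correlation_length, lower = lower)
  field <- g(background)
  for (i in seq_along(lesion_masks)) {
    lf <- g(lesion_models[[i]])
    field[lesion_masks[[i]]] <- lf[lesion_masks[[i]]]
  }
  field
}

#' Generate a multiparametric phantom cohort
#'
#' Each patient gets an ellipsoidal prostate with 1--3 non-overlapping
#' ellipsoidal lesions (multiplicity drawn with probabilities matching a
#' 29:28:5 one/two/three-lesion split), lesion class labels assigned so the
#' cohort has a fixed low:high ratio (default 20:80), voxel-wise parameter
#' fields (ADCk, K, T2, T2w) drawn per tissue class, a 4D DWI series and 4D
#' T2-mapping series synthesized voxel-wise from the kurtosis and T2 decay
#' models with Rician noise, and a T2-weighted volume multiplied by a
#' smooth patient-specific drift field (motivating histogram
#' standardization). Fully reproducible from `seed`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param protocol An [acquisition_protocol()].
#' @param class_models List with `low`, `high`, `background`
#'   [tissue_class_model()]s (default [default_class_models()]).
#' @param drift_amplitude Relative amplitude of the multiplicative T2w
#'   drift field (0 = no drift).
#' @param seed Integer seed; all randomness flows from it.
#' @param lesion_counts Optional integer vector (length `n_patients`) of
#'   lesions per patient; default: sampled from {1,2,3} with probabilities
#'   29/62, 28/62, 5/62.
#' @param low_fraction Fraction of lesions labeled -1 (default 0.2);
#'   exactly `round(low_fraction * n_lesions)` lesions get the low label.
#' @param dwi_sigma,t2_sigma,t2w_sigma Rician noise sigmas for the three
#'   acquisitions, on the scale of the simulated signals (S0 fields are
#'   generated around 1000 a.u. for DWI/T2-series).
#' @return A `phantom_cohort`: list of `phantom_case` objects plus the
#'   generation arguments. Each case carries, per modality, the simulated
#'   volumes, prostate/lesion masks, lesion labels, and the ground-truth
#'   parameter fields under `$truth`.
#' @export
generate_cohort <- function(n_patients, protocol = acquisition_protocol(),
                            class_models = default_class_models(),
                            drift_amplitude = 0.3, seed = 1L,
                            lesion_counts = NULL, low_fraction = 0.2,
                            dwi_sigma = 12, t2_sigma = 12, t2w_sigma = 8) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (is.null(class_models$low) || is.null(class_models$high))
    stop("both lesion class models must be present")
  if (is.null(class_models$background))
    stop("a background tissue model must be present")
  set.seed(as.integer(seed))
  if (is.null(lesion_counts)) {
    lesion_counts <- sample(1:3, n_patients, replace = TRUE,
                            prob = c(29, 28, 5) / 62)
  }
  if (length(lesion_counts) != n_patients || any(!lesion_counts %in% 1:3))
    stop("lesion_counts must give 1-3 lesions per patient")
  n_lesions <- sum(lesion_counts)
  n_low <- round(low_fraction * n_lesions)
  labels <- sample(c(rep(-1, n_low), rep(1, n_lesions - n_low)))
  # one derived sub-seed per patient so cases are independently reproducible
  patient_seeds <- sample.int(.Machine$integer.max, n_patients)
  lab_idx <- cumsum(c(0, lesion_counts))
  cases <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    cases[[p]] <- .generate_case(
      patient_id = p, seed = patient_seeds[p], protocol = protocol,
      class_models = class_models,
      labels = labels[(lab_idx[p] + 1):lab_idx[p + 1]],
      drift_amplitude = drift_amplitude,
      dwi_sigma = dwi_sigma, t2_sigma = t2_sigma, t2w_sigma = t2w_sigma)
  }
  structure(list(cases = cases, protocol = protocol, seed = seed,
                 labels = labels, lesion_counts = lesion_counts),
            class = "phantom_cohort")
}

.generate_case <- function(patient_id, seed, protocol, class_models, labels,
                           drift_amplitude, dwi_sigma, t2_sigma, t2w_sigma) {
  set.seed(seed)
  n_les <- length(labels)
  # prostate: jittered ellipsoid in normalized coordinates, shared by grids
  pr_center <- c(0.5, 0.5, 0.5) + stats::runif(3, -0.03, 0.03)
  pr_radii <- c(0.38, 0.34, 0.40) * stats::runif(3, 0.92, 1.05)
  # lesions: centers inside a shrunken prostate so the ellipsoid stays inside
  les <- vector("list", n_les)
  for (i in seq_len(n_les)) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > 400L) stop("degenerate geometry: could not place disjoint lesions")
      shrink <- 0.9^(attempts %/% 80L) # ease placement when the gland is crowded
      r <- stats::runif(3, c(0.09, 0.09, 0.14), c(0.15, 0.15, 0.26)) * shrink
      if (any(r >= pr_radii)) stop("degenerate geometry: lesion larger than prostate")
      u <- stats::runif(3, -1, 1)
      ctr <- pr_center + u * (pr_radii - r) * 0.85
      ok <- TRUE
      for (j in seq_len(i - 1L)) { # keep lesions disjoint in normalized space
        sep <- sqrt(sum(((ctr - les[[j]]$center) / (r + les[[j]]$radii))^2))
        if (sep < 1.05) ok <- FALSE
      }
      if (ok) { les[[i]] <- list(center = ctr, radii = r); break }
    }
  }
  models <- lapply(labels, function(l)
    if (l < 0) class_models$low else class_models$high)

  build_modality <- function(dm) {
    prostate <- .ellipsoid_mask(dm, pr_center, pr_radii)
    lesion_masks <- lapply(les, function(e) {
      m <- .ellipsoid_mask(dm, e$center, e$radii) & prostate
      m
    })
    for (m in lesion_masks) {
      per_slice <- apply(m, 3, sum)
      if (!any(per_slice > 0)) stop("degenerate geometry: empty lesion mask")
    }
    list(prostate = prostate, lesions = lesion_masks)
  }
  gd <- build_modality(protocol$dwi_dim)
  gt <- build_modality(protocol$t2_dim)
  gw <- build_modality(protocol$t2w_dim)
  bg <- class_models$background

  # ground-truth parameter fields per modality grid
  adc <- .compose_field(protocol$dwi_dim, gd$prostate, gd$lesions, models, bg, "adc", 0.05)
  kk  <- .compose_field(protocol$dwi_dim, gd$prostate, gd$lesions, models, bg, "k", 0.0)
  t2f <- .compose_field(protocol$t2_dim, gt$prostate, gt$lesions, models, bg, "t2", 1)
  t2f <- pmin(t2f, 300)
  t2w <- .compose_field(protocol$t2w_dim, gw$prostate, gw$lesions, models, bg, "t2w", 1)

  # 4D DWI series: S0 field around 1000 a.u., NSA-averaged Rician noise per b
  s0d <- render_textured_field(protocol$dwi_dim, 1000, 0.05, 1.5, lower = 1)
  nb <- length(protocol$b_values)
  dwi <- array(0, c(protocol$dwi_dim, nb))
  for (b in seq_len(nb)) {
    s <- kurtosis_signal(protocol$b_values[b], s0d, adc, kk)
    if (dwi_sigma > 0) {
      acc <- 0
      for (a in seq_len(protocol$nsa[b])) acc <- acc + rician(s, dwi_sigma)
      s <- acc / protocol$nsa[b]
    }
    dwi[, , , b] <- s
  }
  # 4D T2-mapping series
  s0t <- render_textured_field(protocol$t2_dim, 1000, 0.05, 1.5, lower = 1)
  nte <- length(protocol$echo_times)
  t2series <- array(0, c(protocol$t2_dim, nte))
  for (e in seq_len(nte)) {
    s <- t2_signal(protocol$echo_times[e], s0t, t2f)
    if (t2_sigma > 0) s <- rician(s, t2_sigma)
    t2series[, , , e] <- s
  }
  # T2w volume with smooth multiplicative per-patient drift
  drift <- array(1, dim = protocol$t2w_dim)
  if (drift_amplitude > 0) {
    z <- array(stats::rnorm(prod(protocol$t2w_dim)), dim = protocol$t2w_dim)
    z <- .gauss_smooth(z, max(protocol$t2w_dim) / 6)
    z <- z / max(abs(z))
    drift <- 1 + drift_amplitude * z
  }
  t2w_vol <- t2w * drift
  if (t2w_sigma > 0) t2w_vol <- rician(t2w_vol, t2w_sigma)

  structure(list(
    patient_id = patient_id, seed = seed, labels = labels,
    dwi = dwi, t2_series = t2series, t2w = t2w_vol,
    masks = list(dwi = gd, t2 = gt, t2w = gw),
    truth = list(ADCk = adc, K = kk, T2 = t2f, T2w = t2w,
                 S0_dwi = s0d, S0_t2 = s0t, drift = drift)
  ), class = "phantom_case")
}

#' Write a phantom cohort to NIfTI files with a CSV manifest
#'
#' One 4D NIfTI per DWI/T2-mapping series, one 3D NIfTI for the T2w volume,
#' uint8 NIfTI masks per modality, and a `manifest.csv` with patient id,
#' lesion id, label, and file paths.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (case in cohort$cases) {
    pid <- sprintf("p%03d", case$patient_id)
    paths <- c(dwi = file.path(dir, paste0(pid, "_dwi.nii.gz")),
               t2 = file.path(dir, paste0(pid, "_t2series.nii.gz")),
               t2w = file.path(dir, paste0(pid, "_t2w.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(case$dwi), paths["dwi"])
    RNifti::writeNifti(RNifti::asNifti(case$t2_series), paths["t2"])
    RNifti::writeNifti(RNifti::asNifti(case$t2w), paths["t2w"])
    for (mod in c("dwi", "t2", "t2w")) {
      pm <- file.path(dir, paste0(pid, "_", mod, "_prostate.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(case$masks[[mod]]$prostate),
                                               dim = dim(case$masks[[mod]]$prostate))), pm)
      for (i in seq_along(case$masks[[mod]]$lesions)) {
        lm <- file.path(dir, sprintf("%s_%s_lesion%02d.nii.gz", pid, mod, i))
        RNifti::writeNifti(RNifti::asNifti(array(as.integer(case$masks[[mod]]$lesions[[i]]),
                                                 dim = dim(case$masks[[mod]]$lesions[[i]]))), lm)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = case$patient_id, lesion_id = i, label = case$labels[i],
          dwi = paths[["dwi"]], t2_series = paths[["t2"]], t2w = paths[["t2w"]],
          lesion_mask = lm, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
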