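# 2D convolution (correlation with a centered kernel) with replicate padding.
# Kernels are small (<= 19x19) and slices small, so the direct shift-and-add
# loop over kernel elements is fast enough and exact.
.conv2_replicate <- function(x, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr + 2L * hr) - hr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * hc) - hc, 1L), nc)
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    w <- kern[a, b]
    if (w == 0) next
    out <- out + w * xp[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

#' Gabor filter kernel
#'
#' Complex kernel `exp(-(x^2+y^2)/(2 sigma^2)) * exp(2 pi i f (x cos(theta)
#' + y sin(theta)))` with a circular Gaussian envelope, sampled on a square
#' support of half-size `ceiling(3 sigma)`.
#'
#' @param frequency Sinusoid frequency in cycles/voxel.
#' @param sigma Gaussian envelope standard deviation in voxels.
#' @param theta Orientation in radians.
#' @return Complex matrix.
#' @export
gabor_kernel <- function(frequency, sigma, theta) {
  r <- ceiling(3 * sigma)
  xs <- -r:r
  gx <- matrix(xs, length(xs), length(xs))
  gy <- t(gx)
  env <- exp(-(gx^2 + gy^2) / (2 * sigma^2))
  env * exp(2i * pi * frequency * (gx * cos(theta) + gy * sin(theta)))
}

#' Orientation-summed Gabor response maps of a slice
#'
#' For every combination of five frequencies (0.1--0.5 cycles/voxel) and
#' three envelope sizes (sigma = 1, 2, 3), the complex responses at the
#' four bidirectional orientations 0, 45, 90, 135 degrees are summed into
#' one complex image (a simple orientation-invariant scheme: the 90-degree
#' rotation of a slice rotates its summed maps). Windowed statistics of
#' these maps (mean of the real part, variance of the real part, mean
#' absolute real part, mean magnitude) form the Gabor features.
#'
#' @param slice Numeric matrix.
#' @param frequencies,sigmas Filter-bank parameters.
#' @return Named list of complex matrices, one per `f<frequency>_s<sigma>`.
#' @export
gabor_response_maps <- function(slice, frequencies = seq(0.1, 0.5, by = 0.1),
                                sigmas = 1:3) {
  thetas <- c(0, 45, 90, 135) * pi / 180
  out <- list()
  for (f in frequencies) for (s in sigmas) {
    acc <- matrix(0 + 0i, nrow(slice), ncol(slice))
    for (th in thetas) {
      k <- gabor_kernel(f, s, th)
      acc <- acc + .conv2_replicate(slice, Re(k)) +
        1i * .conv2_replicate(slice, Im(k))
    }
    out[[sprintf("f%.1f_s%d", f, s)]] <- acc
  }
  out
}

#' Per-window statistics of one Gabor response map
#'
#' @param gmap Complex matrix from [gabor_response_maps()].
#' @param rows,cols Window position (top-left corner) and `w` side length.
#' @param w Window side length.
#' @return Numeric vector: `mean_real`, `var_real`, `mean_abs_real`,
#'   `mean_magnitude`.
#' @export
gabor_window_stats <- function(gmap, rows, cols, w) {
  sub <- gmap[rows:(rows + w - 1L), cols:(cols + w - 1L)]
  re <- Re(sub)
  c(mean_real = mean(re),
    var_real = stats::var(as.numeric(re)),
    mean_abs_real = mean(abs(re)),
    mean_magnitude = mean(Mod(sub)))
}

# One level of the 2D Haar transform (orthonormal): returns the four
# quarter-size coefficient planes of an even-dimension matrix.
.haar_level <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  a <- (x[seq(1, nr, 2), , drop = FALSE] + x[seq(2, nr, 2), , drop = FALSE]) / sqrt(2)
  d <- (x[seq(1, nr, 2), , drop = FALSE] - x[seq(2, nr, 2), , drop = FALSE]) / sqrt(2)
  ll <- (a[, seq(1, nc, 2), drop = FALSE] + a[, seq(2, nc, 2), drop = FALSE]) / sqrt(2)
  lh <- (a[, seq(1, nc, 2), drop = FALSE] - a[, seq(2, nc, 2), drop = FALSE]) / sqrt(2)
  hl <- (d[, seq(1, nc, 2), drop = FALSE] + d[, seq(2, nc, 2), drop = FALSE]) / sqrt(2)
  hh <- (d[, seq(1, nc, 2), drop = FALSE] - d[, seq(2, nc, 2), drop = FALSE]) / sqrt(2)
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

.nn_upscale <- function(x, target_nr, target_nc) {
  ri <- pmin(ceiling(seq_len(target_nr) * nrow(x) / target_nr), nrow(x))
  ci <- pmin(ceiling(seq_len(target_nc) * ncol(x) / target_nc), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Haar wavelet detail planes of a slice
#'
#' Four-level 2D Haar decomposition; the slice is edge-replicated to the
#' next multiple of 16 beforehand. The three detail planes (LH, HL, HH) of
#' each level are nearest-neighbor upscaled back to the slice size, giving
#' 12 coefficient maps. Per sliding window, the mean absolute value and the
#' standard deviation of each map yield 24 Haar features. A constant slice
#' has all detail coefficients equal to 0.
#'
#' @param slice Numeric matrix.
#' @param levels Number of decomposition levels (default 4).
#' @return Named list of 12 matrices (`L<level>_<lh|hl|hh>`), slice-sized.
#' @export
haar_detail_planes <- function(slice, levels = 4L) {
  nr <- nrow(slice); nc <- ncol(slice)
  mult <- 2^levels
  pr <- ceiling(nr / mult) * mult
  pc <- ceiling(nc / mult) * mult
  x <- slice[pmin(seq_len(pr), nr), pmin(seq_len(pc), nc), drop = FALSE]
  out <- list()
  for (lv in seq_len(levels)) {
    hl <- .haar_level(x)
    for (pl in c("lh", "hl", "hh"))
      out[[sprintf("L%d_%s", lv, pl)]] <- .nn_upscale(hl[[pl]], nr, nc)
    x <- hl$ll
  }
  out
}

#' Hu moment invariants of a patch
#'
#' The seven Hu invariants of the patch's intensity distribution, returned
#' as `log(|h|)` with magnitudes below 1e-30 floored there (keeps the
#' features bounded when an invariant vanishes). The invariants are
#' unchanged under translation, scaling, rotation, and (in absolute value)
#' reflection.
#'
#' @param patch Numeric matrix of non-negative intensities.
#' @return Numeric vector `hu1`..`hu7` of log absolute invariants.
#' @export
hu_moments <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1, nr, nc)
  m00 <- sum(patch)
  if (m00 == 0) return(stats::setNames(rep(log(1e-30), 7), paste0("hu", 1:7)))
  xb <- sum(x * patch) / m00
  yb <- sum(y * patch) / m00
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * patch)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- numeric(7)
  h[1] <- n20 + n02
  h[2] <- (n20 - n02)^2 + 4 * n11^2
  h[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h[4] <- (n30 + n12)^2 + (n21 + n03)^2
  h[5] <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h[7] <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  stats::setNames(log(pmax(abs(h), 1e-30)), paste0("hu", 1:7))
}

#' Zernike (n, m) index pairs up to a given degree
#'
#' All pairs with `0 <= m <= n`, `n - m` even, in (n, m) lexicographic
#' order; degree 8 yields 25 pairs.
#'
#' @param max_degree Maximum radial degree n (default 8).
#' @return Two-column integer matrix with columns `n`, `m`.
#' @export
zernike_indices <- function(max_degree = 8L) {
  idx <- list()
  for (n in 0:max_degree) for (m in 0:n) if ((n - m) %% 2L == 0L)
    idx[[length(idx) + 1L]] <- c(n = n, m = m)
  do.call(rbind, idx)
}

# Radial polynomial R_nm(rho)
.zernike_radial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

#' Zernike basis for a square window
#'
#' Complex conjugate basis values `V*_nm` sampled at the window's pixels
#' inside the unit disk of radius `w/2` centered on the window center,
#' scaled by `(n+1)/pi` and the pixel area in unit-disk coordinates, so
#' that a patch-vector inner product yields the Zernike moment. Precompute
#' once per window size and reuse across positions.
#'
#' @param w Window side length (voxels).
#' @param max_degree Maximum radial degree (default 8).
#' @return List with `basis` (pixels-in-disk x 25 complex matrix),
#'   `inside` (logical w*w vector, column-major), and `indices`.
#' @export
zernike_basis <- function(w, max_degree = 8L) {
  ctr <- (w + 1) / 2
  rad <- w / 2
  xs <- (seq_len(w) - ctr) / rad
  gx <- matrix(xs, w, w, byrow = TRUE) # x varies along columns
  gy <- matrix(xs, w, w)               # y along rows
  rho <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  inside <- as.vector(rho <= 1)
  idx <- zernike_indices(max_degree)
  basis <- matrix(0 + 0i, sum(inside), nrow(idx))
  area <- (2 / w)^2 # pixel area in unit-disk coordinates
  for (k in seq_len(nrow(idx))) {
    n <- idx[k, "n"]; m <- idx[k, "m"]
    vals <- .zernike_radial(n, m, rho) * exp(-1i * m * theta)
    basis[, k] <- vals[inside] * (n + 1) / pi * area
  }
  list(basis = basis, inside = inside, indices = idx)
}

#' Zernike moment magnitudes of a patch
#'
#' Magnitudes of the complex Zernike moments up to the 8th degree (25
#' values in (n, m) lexicographic order), computed over the unit disk
#' inscribed in the window. Magnitudes are rotation invariant.
#'
#' @param patch Square numeric matrix.
#' @param basis Optional precomputed [zernike_basis()] for `nrow(patch)`.
#' @return Named numeric vector of 25 magnitudes (`z<n>_<m>`).
#' @export
zernike_moments <- function(patch, basis = NULL) {
  w <- nrow(patch)
  if (ncol(patch) != w) stop("patch must be square")
  if (is.null(basis)) basis <- zernike_basis(w)
  v <- as.vector(patch)[basis$inside]
  mags <- Mod(as.vector(t(basis$basis) %*% v))
  names(mags) <- sprintf("z%d_%d", basis$indices[, "n"], basis$indices[, "m"])
  mags
}

#' Moment features of a patch
#'
#' Dispatcher used by the texture bank: `kind = "hu"` returns the 7 Hu
#' log-invariants, `kind = "zernike"` the 25 Zernike magnitudes.
#'
#' @param patch Square numeric matrix.
#' @param kind `"hu"` or `"zernike"`.
#' @param basis Optional precomputed Zernike basis.
#' @return Numeric vector of 7 or 25 values.
#' @export
moment_features <- function(patch, kind = c("hu", "zernike"), basis = NULL) {
  kind <- match.arg(kind)
  if (kind == "hu") hu_moments(patch) else zernike_moments(patch, basis)
}
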