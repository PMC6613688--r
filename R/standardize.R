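#' Landmark percentile positions used for histogram standardization
#'
#' The deciles p10..p90 as landmarks, framed by robust scale endpoints at
#' the 1st and 99th in-mask percentiles (robust minimum/maximum; plain
#' min/max would let single outlier voxels stretch the standard scale).
#'
#' @return Numeric vector of probabilities.
#' @export
landmark_positions <- function() c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)

.image_landmarks <- function(image, mask) {
  v <- image[mask]
  if (length(v) == 0L) stop("empty prostate mask")
  stats::quantile(v, probs = landmark_positions(), names = FALSE, type = 7)
}

#' Learn a standard intensity scale from a cohort of T2w images
#'
#' Computes each image's in-prostate landmark intensities (deciles plus
#' robust endpoints) and averages them landmark-wise across images; the
#' mean landmark vector is the standard scale every image is mapped onto.
#' Only voxels inside the prostate mask contribute.
#'
#' @param images List of 3D arrays.
#' @param prostate_masks List of 3D logical arrays, same lengths/dims.
#' @return Object of class `landmark_set` with `positions`,
#'   `per_image` (images x landmarks matrix) and `standard` (mean scale).
#' @export
learn_standard_scale <- function(images, prostate_masks) {
  if (length(images) < 1L) stop("need at least one image")
  if (length(images) != length(prostate_masks)) stop("images/masks length mismatch")
  lm <- t(mapply(.image_landmarks, images, prostate_masks))
  standard <- colMeans(lm)
  if (any(diff(standard) < 0)) stop("standard-scale landmarks are not non-decreasing")
  structure(list(positions = landmark_positions(), per_image = lm,
                 standard = standard), class = "landmark_set")
}

# Piecewise-linear map through (x_i, y_i) with linear extrapolation from the
# end segments. Duplicate x knots (possible on heavily quantized images) are
# collapsed to their mean y.
.piecewise_map <- function(values, x, y) {
  keep <- !duplicated(x)
  if (sum(keep) < 2L) stop("degenerate image: constant inside the mask")
  if (any(!keep)) {
    y <- vapply(split(y, match(x, unique(x))), mean, numeric(1))
    x <- unique(x)
  }
  n <- length(x)
  out <- stats::approx(x, y, xout = values, rule = 2)$y
  lo <- values < x[1]
  hi <- values > x[n]
  if (any(lo)) out[lo] <- y[1] + (values[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  if (any(hi)) out[hi] <- y[n] + (values[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  out
}

#' Standardize a T2w image onto a learned standard scale
#'
#' Maps the image's own in-mask landmarks onto the standard landmarks with
#' a piecewise-linear transform, applied to every voxel of the image;
#' values beyond the outer landmarks are extrapolated linearly from the end
#' segments. The map is non-decreasing, so voxel rank order inside the
#' mask is preserved, and re-standardizing an already standardized image is
#' the identity (to numerical tolerance).
#'
#' @param image 3D array.
#' @param prostate_mask 3D logical array.
#' @param standard_scale A `landmark_set` from [learn_standard_scale()], or
#'   a bare numeric vector of standard landmark intensities.
#' @return Standardized image, same dimensions.
#' @export
standardize_image <- function(image, prostate_mask, standard_scale) {
  std <- if (inherits(standard_scale, "landmark_set")) standard_scale$standard
         else as.numeric(standard_scale)
  if (length(std) != length(landmark_positions()))
    stop("standard scale has wrong number of landmarks")
  own <- .image_landmarks(image, prostate_mask)
  if (own[1] == own[length(own)]) stop("degenerate image: constant inside the mask")
  out <- .piecewise_map(as.numeric(image), own, std)
  dim(out) <- dim(image)
  out
}

#' Persist / load a learned standard scale
#'
#' Writes the landmark positions and standard intensities to a small JSON
#' sidecar so learning and application can run as separate steps.
#'
#' @param scale A `landmark_set`.
#' @param path JSON file path.
#' @return `write_standard_scale`: `path`, invisibly.
#'   `read_standard_scale`: a `landmark_set` (without per-image landmarks).
#' @export
write_standard_scale <- function(scale, path) {
  jsonlite::write_json(list(positions = scale$positions,
                            standard = scale$standard),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_standard_scale
#' @export
read_standard_scale <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(positions = x$positions, per_image = NULL,
                 standard = x$standard), class = "landmark_set")
}
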