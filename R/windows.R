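#' Sliding-window side lengths per image class
#'
#' Seven odd window sizes 3, 5, ..., 15 voxels for the DWI-resolution
#' parametric maps (ADCm, ADCk, K) and nine sizes 3, 7, ..., 35 for the
#' higher-resolution T2w and T2 images, keeping similar physical coverage
#' across resolutions.
#'
#' @param image_type One of `"T2w"`, `"ADCm"`, `"ADCk"`, `"K"`, `"T2"`.
#' @return Integer vector of window side lengths.
#' @export
window_grid <- function(image_type) {
  if (image_type %in% c("ADCm", "ADCk", "K")) return(seq(3L, 15L, by = 2L))
  if (image_type %in% c("T2w", "T2")) return(seq(3L, 35L, by = 4L))
  stop("unknown image type: ", image_type)
}

# Summed-area table with a zero top/left border, so window sums are O(1).
.sat <- function(m) {
  s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  s[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  s
}

.sat_window_sum <- function(s, r, c, w) {
  s[r + w, c + w] - s[r, c + w] - s[r + w, c] + s[r, c]
}

#' Valid sliding-window positions on one slice
#'
#' Centers whose w x w window lies completely inside the lesion on this
#' slice (and inside the slice bounds). If the window fits nowhere but the
#' slice has lesion voxels, the fallback returns every in-bounds position
#' maximizing the in-window lesion-voxel count (all ties kept).
#'
#' @param mask Logical matrix (one slice of the lesion mask).
#' @param w Window side length (odd, `w <= min(dim(mask))` required for
#'   any position to exist).
#' @return List with `tl` (two-column matrix of top-left corners, possibly
#'   zero rows), and `fallback` (TRUE if the max-overlap rule engaged).
#' @export
window_positions <- function(mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask) || w > nr || w > nc)
    return(list(tl = matrix(integer(0), 0, 2), fallback = FALSE))
  s <- .sat(mask * 1)
  nrp <- nr - w + 1L; ncp <- nc - w + 1L
  counts <- s[(w + 1):(nr + 1), (w + 1):(nc + 1), drop = FALSE] -
    s[1:nrp, (w + 1):(nc + 1), drop = FALSE] -
    s[(w + 1):(nr + 1), 1:ncp, drop = FALSE] +
    s[1:nrp, 1:ncp, drop = FALSE]
  full <- which(counts == w * w, arr.ind = TRUE)
  if (nrow(full) > 0L) return(list(tl = unname(full), fallback = FALSE))
  mx <- max(counts)
  if (mx == 0) return(list(tl = matrix(integer(0), 0, 2), fallback = FALSE))
  list(tl = unname(which(counts == mx, arr.ind = TRUE)), fallback = TRUE)
}

#' Aggregate per-position texture values into one lesion-wise value
#'
#' Default pools the valid-position values of all slices and takes the
#' median; the alternative takes the median per slice and then the mean
#' over slices.
#'
#' @param per_slice_values List with one numeric vector per slice (slices
#'   without valid positions may be NULL or empty).
#' @param mode `"pooled_median"` or `"slice_mean"`.
#' @return Single numeric value.
#' @export
aggregate_lesion <- function(per_slice_values,
                             mode = c("pooled_median", "slice_mean")) {
  mode <- match.arg(mode)
  keep <- Filter(function(v) length(v) > 0L, per_slice_values)
  if (length(keep) == 0L) stop("no valid positions on any slice")
  if (mode == "pooled_median") return(stats::median(unlist(keep)))
  mean(vapply(keep, stats::median, numeric(1)))
}
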