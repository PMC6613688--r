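#' Quantize an image to discrete gray levels
#'
#' Uniformly bins values clipped to `[range[1], range[2]]` into
#' `{0, ..., n_levels-1}` by `floor((x - lo) / (hi - lo) * n_levels)`, with
#' the upper bound mapped to the top level. A constant image at the range
#' midpoint therefore maps to level `n_levels/2` (16 at 32 levels).
#'
#' @param x Numeric matrix/array.
#' @param range Length-2 numeric, lower < upper.
#' @param n_levels Number of gray levels (default 32).
#' @return Integer array of the same shape with values in
#'   `0..n_levels-1`.
#' @export
quantize <- function(x, range, n_levels = 32L) {
  if (range[1] >= range[2]) stop("inverted quantization range")
  v <- pmin(pmax(x, range[1]), range[2])
  g <- floor((v - range[1]) / (range[2] - range[1]) * n_levels)
  g[g == n_levels] <- n_levels - 1L
  storage.mode(g) <- "integer"
  g
}

.glcm_feature_names <- c("contrast", "dissimilarity", "homogeneity",
                         "energy", "correlation", "asm")

# Accumulate the symmetric normalized co-occurrence matrix for one offset
# (dr, dc) on an integer matrix; NA cells (masked-out voxels) never pair.
.cooc_counts <- function(q, dr, dc, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  if (abs(dr) >= nr || abs(dc) >= nc) return(NULL) # offset exceeds patch
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  if (anyNA(a) || anyNA(b)) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NULL)
    a <- a[ok]; b <- b[ok]
  }
  counts <- tabulate(a * n_levels + b + 1L, nbins = n_levels * n_levels)
  cm <- matrix(counts, n_levels, n_levels, byrow = TRUE) # rows = first pixel
  cm + t(cm) # symmetric
}

# level-value matrices for Haralick evaluation over the gray values `lev`
# actually present in a patch (unoccupied levels contribute nothing, so the
# co-occurrence matrix can be restricted to the active levels)
.haralick_consts <- function(lev) {
  dif <- outer(lev, lev, `-`)
  list(lev = lev, dif2 = dif^2, absd = abs(dif),
       hom = 1 / (1 + dif^2), ij = outer(lev, lev))
}

.haralick6 <- function(P, cst = .haralick_consts(seq_len(nrow(P)) - 1)) {
  contrast <- sum(P * cst$dif2)
  dissim <- sum(P * cst$absd)
  homog <- sum(P * cst$hom)
  asm <- sum(P * P)
  rs <- .rowSums(P, nrow(P), ncol(P))
  cs <- .colSums(P, nrow(P), ncol(P))
  mu_i <- sum(cst$lev * rs); mu_j <- sum(cst$lev * cs)
  var_i <- sum(cst$lev^2 * rs) - mu_i^2
  var_j <- sum(cst$lev^2 * cs) - mu_j^2
  denom <- sqrt(max(var_i, 0) * max(var_j, 0))
  corr <- if (denom == 0) 1 else (sum(P * cst$ij) - mu_i * mu_j) / denom
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = sqrt(asm), correlation = corr, asm = asm)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, normalized co-occurrence at one voxel distance over the four
#' bidirectional orientations 0, 45, 90, 135 degrees. For each of the six
#' Haralick features (contrast, dissimilarity, homogeneity, energy,
#' correlation, angular second moment), the mean over orientations and the
#' range over orientations are returned: 12 values. In `mbb` mode the patch
#' is the lesion's minimum bounding box and `mask` marks lesion voxels;
#' non-lesion voxels never form pairs. If an orientation (or all of them)
#' yields no valid pair, its features are 0 (correlation included).
#'
#' @param q Integer matrix of gray levels in `0..n_levels-1` (NA allowed in
#'   `mbb` mode outside the mask).
#' @param distance Co-occurrence distance in voxels (>= 1).
#' @param mode `"window"` (full patch) or `"mbb"` (masked bounding box).
#' @param mask Logical matrix, required in `mbb` mode.
#' @param n_levels Number of gray levels (default 32).
#' @return Named numeric vector of 12 values
#'   (`<feature>_mean`, `<feature>_range` for each Haralick feature).
#' @export
glcm_features <- function(q, distance = 1L, mode = c("window", "mbb"),
                          mask = NULL, n_levels = 32L) {
  mode <- match.arg(mode)
  if (distance < 1) stop("distance must be >= 1")
  if (mode == "mbb") {
    if (is.null(mask)) stop("mbb mode requires a mask")
    q[!mask] <- NA_integer_
  }
  # restrict to the gray levels actually present: unoccupied levels carry no
  # co-occurrence mass, and the Haralick features depend on level values only
  # through occupied cells
  u <- sort(unique(q[!is.na(q)]))
  if (length(u) == 0L) {
    out <- numeric(12L)
    names(out) <- as.vector(rbind(paste0(.glcm_feature_names, "_mean"),
                                  paste0(.glcm_feature_names, "_range")))
    return(out)
  }
  qc <- q
  qc[] <- match(q, u) - 1L
  k <- length(u)
  cst <- .haralick_consts(as.numeric(u))
  d <- as.integer(distance)
  offsets <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d)) # 0,45,90,135 deg
  per_orient <- matrix(0, nrow = 4L, ncol = 6L,
                       dimnames = list(NULL, .glcm_feature_names))
  for (o in seq_along(offsets)) {
    cc <- .cooc_counts(qc, offsets[[o]][1], offsets[[o]][2], k)
    if (is.null(cc)) next # leave zeros: no valid pairs
    per_orient[o, ] <- .haralick6(cc / sum(cc), cst)
  }
  means <- colMeans(per_orient)
  ranges <- apply(per_orient, 2, function(v) max(v) - min(v))
  out <- as.numeric(rbind(means, ranges))
  names(out) <- as.vector(rbind(paste0(.glcm_feature_names, "_mean"),
                                paste0(.glcm_feature_names, "_range")))
  out
}

# Batched sliding-window GLCM: 12 Haralick summaries for every top-left
# corner in `tl` at window size `w`, one 12 x np matrix per distance.
# Contrast/dissimilarity/homogeneity/correlation moments are linear in the
# co-occurrence counts, so they come from summed-area tables over per-pair
# value maps; only ASM/energy need a per-position pair histogram. Agrees
# with glcm_features() on every window (tested against it).
.glcm_windowed_batch <- function(q, tl, w, dists) {
  u <- sort(unique(as.vector(q)))
  k <- length(u)
  qc <- q
  qc[] <- match(q, u) - 1L
  uv <- as.numeric(u)
  np <- nrow(tl)
  tidx <- {
    a <- rep(0:(k - 1), each = k); b <- rep.int(0:(k - 1), k)
    b * k + a + 1L
  }
  r0 <- tl[, 1]; c0 <- tl[, 2]
  out <- lapply(dists, function(d) {
    m <- matrix(0, 12L, np)
    rownames(m) <- as.vector(rbind(paste0(.glcm_feature_names, "_mean"),
                                   paste0(.glcm_feature_names, "_range")))
    m
  })
  names(out) <- as.character(dists)
  for (d in dists) {
    offs <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
    per_or <- array(0, c(4L, 6L, np))
    for (o in 1:4) {
      dr <- offs[[o]][1]; dc <- offs[[o]][2]
      h <- w - abs(dr); wd <- w - abs(dc)
      if (h < 1L || wd < 1L) next # distance exceeds window: no pairs
      ar <- (1L + max(0L, -dr)):(nrow(q) - max(0L, dr))
      ac <- (1L + max(0L, -dc)):(ncol(q) - max(0L, dc))
      a <- qc[ar, ac, drop = FALSE]
      b <- qc[ar + dr, ac + dc, drop = FALSE]
      va <- uv[a + 1L]; dim(va) <- dim(a)
      vb <- uv[b + 1L]; dim(vb) <- dim(b)
      dif <- va - vb
      rs <- function(s) s[cbind(r0 + h, c0 + wd)] - s[cbind(r0, c0 + wd)] -
        s[cbind(r0 + h, c0)] + s[cbind(r0, c0)]
      npair <- h * wd          # one-directional pairs per window
      N <- 2 * npair           # symmetric count total
      contrast <- rs(.sat(dif^2)) / npair
      dissim <- rs(.sat(abs(dif))) / npair
      homog <- rs(.sat(1 / (1 + dif^2))) / npair
      mu <- rs(.sat(va + vb)) / N
      ex2 <- rs(.sat(va^2 + vb^2)) / N
      vvar <- pmax(ex2 - mu^2, 0)
      exy <- rs(.sat(2 * va * vb)) / N
      # guard against SAT rounding residue on (near-)constant windows
      corr <- ifelse(vvar > 1e-10 * pmax(ex2, 1), (exy - mu^2) / vvar, 1)
      codes <- a * k + b + 1L
      asm <- numeric(np)
      nb <- k * k
      for (i in seq_len(np)) {
        tb <- tabulate(codes[r0[i]:(r0[i] + h - 1L),
                             c0[i]:(c0[i] + wd - 1L)], nbins = nb)
        tsym <- tb + tb[tidx]
        asm[i] <- sum(tsym * tsym) / (N * N)
      }
      per_or[o, 1, ] <- contrast
      per_or[o, 2, ] <- dissim
      per_or[o, 3, ] <- homog
      per_or[o, 4, ] <- sqrt(asm)
      per_or[o, 5, ] <- corr
      per_or[o, 6, ] <- asm
    }
    res <- out[[as.character(d)]]
    for (f in 1:6) {
      vals <- per_or[, f, , drop = FALSE]
      dim(vals) <- c(4L, np)
      res[2L * f - 1L, ] <- .colMeans(vals, 4L, np)
      res[2L * f, ] <- apply(vals, 2, max) - apply(vals, 2, min)
    }
    out[[as.character(d)]] <- res
  }
  out
}

# riu2 code of one pixel: 8 bilinearly interpolated neighbors on a circle of
# radius r; bit = neighbor >= center; uniform patterns (<= 2 circular 0/1
# transitions) coded by their number of ones (0..8), non-uniform = 9.
.lbp_code <- function(patch, row, col, radius, n_points = 8L) {
  ctr <- patch[row, col]
  ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
  rr <- row + radius * sin(ang)
  cc <- col + radius * cos(ang)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  nr <- nrow(patch); nc <- ncol(patch)
  gv <- function(r, c) patch[pmin(pmax(r, 1L), nr) + (pmin(pmax(c, 1L), nc) - 1L) * nr]
  val <- (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1L) +
         fr * (1 - fc) * gv(r0 + 1L, c0) + fr * fc * gv(r0 + 1L, c0 + 1L)
  bits <- as.integer(val >= ctr - 1e-9 * max(abs(ctr), 1))
  trans <- sum(bits != c(bits[-1], bits[1]))
  if (trans <= 2L) sum(bits) else 9L
}

#' Rotation-invariant uniform LBP histogram of a patch
#'
#' Local binary pattern codes with 8 interpolated neighbors at the maximum
#' radius the window allows (`(w-1)/2` for a w x w patch), computed at
#' every pixel whose full circle fits inside the patch (for the maximum
#' radius that is the center pixel alone). Uniform patterns are grouped by
#' their number of ones (rotation-invariant, bins 0..8); all non-uniform
#' patterns share one bin. The returned 10-bin histogram is normalized to
#' sum 1. A constant patch lands entirely in bin 8 (neighbors compare `>=`
#' against the center).
#'
#' @param patch Numeric matrix (square window).
#' @param n_points Number of circle points (default 8).
#' @param radius Circle radius; default `(min(dim(patch)) - 1) / 2`.
#' @return Numeric vector of 10 normalized frequencies
#'   (`riu0`..`riu8`, `nonuniform`).
#' @export
lbp_histogram <- function(patch, n_points = 8L,
                          radius = (min(dim(patch)) - 1) / 2) {
  if (min(dim(patch)) < 3L) stop("patch must be at least 3x3")
  nr <- nrow(patch); nc <- ncol(patch)
  rmin <- ceiling(1 + radius); rmax <- floor(nr - radius)
  cmin <- ceiling(1 + radius); cmax <- floor(nc - radius)
  codes <- integer(0)
  for (r in rmin:rmax) for (c in cmin:cmax)
    codes <- c(codes, .lbp_code(patch, r, c, radius, n_points))
  h <- tabulate(codes + 1L, nbins = 10L)
  h <- h / sum(h)
  names(h) <- c(paste0("riu", 0:8), "nonuniform")
  h
}

#' Histogram-of-oriented-gradients scalar for one window
#'
#' The window is a single HOG cell with eight unsigned orientation bins
#' (22.5 degree width over [0, 180)); gradients come from central
#' differences and votes are magnitude-weighted. The 8-bin histogram is
#' L2-normalized and summarized as its maximum bin value (a scalar in
#' [sqrt(1/8), 1] measuring gradient-direction concentration); a
#' zero-gradient window returns 0.
#'
#' @param patch Numeric matrix.
#' @return Single numeric value.
#' @export
hog_feature <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (nr < 3L || nc < 3L) stop("window must be >= 3x3")
  gx <- (patch[, c(2:nc, nc)] - patch[, c(1, 1:(nc - 1))]) / 2
  gy <- (patch[c(2:nr, nr), ] - patch[c(1, 1:(nr - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(0)
  ang <- atan2(gy, gx) %% pi # unsigned orientation in [0, pi)
  bin <- pmin(floor(ang / (pi / 8)), 7) + 1L
  h <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1))
  h <- h / sqrt(sum(h^2))
  max(h)
}

.sobel_magnitude <- function(slice) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- .conv2_replicate(slice, kx)
  gy <- .conv2_replicate(slice, t(kx))
  sqrt(gx^2 + gy^2)
}

# 4-connected erosion of a binary matrix (treats outside as background)
.erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  ctr & pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
}

#' Sobel gradient-magnitude features of a lesion
#'
#' Computes the 3x3 Sobel gradient magnitude per transverse slice and
#' takes the median over the lesion voxels pooled across slices, once with
#' lesion edge voxels included and once with a 1-voxel (4-connected)
#' erosion removing them. If erosion empties the mask on every slice, the
#' edge-excluded value falls back to the edge-included one.
#'
#' @param slices 3D array (or a single 2D matrix).
#' @param lesion_mask Logical array, same shape.
#' @return Numeric vector `c(median_all, median_eroded)`.
#' @export
sobel_features <- function(slices, lesion_mask) {
  if (is.matrix(slices)) {
    slices <- array(slices, dim = c(dim(slices), 1))
    lesion_mask <- array(lesion_mask, dim = dim(slices))
  }
  vals_all <- numeric(0); vals_in <- numeric(0)
  for (z in seq_len(dim(slices)[3])) {
    m <- lesion_mask[, , z]
    if (!any(m)) next
    g <- .sobel_magnitude(slices[, , z])
    vals_all <- c(vals_all, g[m])
    er <- .erode4(m)
    if (any(er)) vals_in <- c(vals_in, g[er])
  }
  if (length(vals_all) == 0L) stop("empty lesion mask")
  v1 <- stats::median(vals_all)
  v2 <- if (length(vals_in) > 0L) stats::median(vals_in) else v1
  c(sobel_median = v1, sobel_median_inner = v2)
}

#' First-order statistics of lesion intensities
#'
#' Exactly 18 values: mean, standard deviation, range, minimum, maximum,
#' the percentiles 10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90 (deciles and
#' quartiles with the median counted once), kurtosis and skewness.
#' Percentiles use the linear-interpolation convention (R type 7).
#' Skewness is `m3/s^3` and kurtosis is excess kurtosis `m4/s^4 - 3` with
#' population moments; both are defined as 0 for constant input.
#'
#' @param values Numeric vector (>= 1 value).
#' @return Named numeric vector of length 18.
#' @export
first_order_stats <- function(values) {
  if (length(values) == 0L) stop("empty input")
  qs <- stats::quantile(values, probs = c(.10, .20, .25, .30, .40, .50,
                                          .60, .70, .75, .80, .90),
                        names = FALSE, type = 7)
  s <- stats::sd(values)
  if (length(values) == 1L) s <- 0
  m <- mean(values)
  if (s == 0) { skew <- 0; kurt <- 0 } else {
    z <- (values - m)
    m2 <- mean(z^2)
    skew <- mean(z^3) / m2^1.5
    kurt <- mean(z^4) / m2^2 - 3
  }
  out <- c(mean = m, sd = s, range = max(values) - min(values),
           min = min(values), max = max(values),
           p10 = qs[1], p20 = qs[2], p25 = qs[3], p30 = qs[4], p40 = qs[5],
           p50 = qs[6], p60 = qs[7], p70 = qs[8], p75 = qs[9], p80 = qs[10],
           p90 = qs[11], kurtosis = kurt, skewness = skew)
  names(out) <- c("mean", "sd", "range", "min", "max", "p10", "p20", "p25",
                  "p30", "p40", "p50", "p60", "p70", "p75", "p80", "p90",
                  "kurtosis", "skewness")
  out
}
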