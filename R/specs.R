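.image_types <- c("T2w", "ADCm", "ADCk", "K", "T2")

.glcm_distances <- function(w) seq_len(min(w, 4L)) # window 3 -> {1,2,3}

.lbp_bins <- c(paste0("riu", 0:8), "nonuniform")
.gabor_stats <- c("mean_real", "var_real", "mean_abs_real", "mean_magnitude")
.haar_planes <- as.vector(outer(c("lh", "hl", "hh"), 1:4,
                                function(p, l) sprintf("L%d_%s", l, p)))
.stat_names <- c("mean", "sd", "range", "min", "max", "p10", "p20", "p25",
                 "p30", "p40", "p50", "p60", "p70", "p75", "p80", "p90",
                 "kurtosis", "skewness")
.glcm_value_names <- as.vector(rbind(
  paste0(c("contrast", "dissimilarity", "homogeneity", "energy",
           "correlation", "asm"), "_mean"),
  paste0(c("contrast", "dissimilarity", "homogeneity", "energy",
           "correlation", "asm"), "_range")))

#' Enumerate the full feature bank for one image type
#'
#' Deterministic, documented ordering: first-order statistics (18, lesion
#' wide), then sliding-window GLCM (12 values per window and distance,
#' distances 1..min(window, 4)), minimum-bounding-box GLCM (4 distances x
#' 12), LBP (10 histogram bins per window), Gabor (5 frequencies x 3 sigmas
#' x 4 statistics per window), Haar (4 levels x 3 detail planes x 2
#' statistics per window), Hu moments (7 per window), Zernike moments (25
#' per window), HOG (1 per window), and Sobel (2, lesion wide). Within a
#' method, windows ascend, then parameters, then the statistic. This
#' yields 1281 features for each DWI-resolution type (ADCm, ADCk, K) and
#' 1631 for T2w and T2; 7105 over all five types.
#'
#' @param image_type One of `"T2w"`, `"ADCm"`, `"ADCk"`, `"K"`, `"T2"`.
#' @return A data.frame with columns `image_type`, `method`, `window`
#'   (NA for lesion-wide methods), `params`, `stat`, and the canonical
#'   `name` string `<imagetype>:<method>(<params>):w<size>:<stat>`.
#' @export
enumerate_feature_specs <- function(image_type) {
  if (!image_type %in% .image_types) stop("unknown image type: ", image_type)
  ws <- window_grid(image_type)
  rows <- list()
  add <- function(method, window, params, stat) {
    wtag <- if (is.na(window)) "w0" else paste0("w", window)
    ptag <- if (params == "") "()" else paste0("(", params, ")")
    rows[[length(rows) + 1L]] <<- data.frame(
      image_type = image_type, method = method, window = window,
      params = params, stat = stat,
      name = paste0(image_type, ":", method, ptag, ":", wtag, ":", stat),
      stringsAsFactors = FALSE)
  }
  for (s in .stat_names) add("stats", NA_integer_, "", s)
  for (w in ws) for (d in .glcm_distances(w)) for (v in .glcm_value_names)
    add("glcm", w, paste0("d=", d), v)
  for (d in 1:4) for (v in .glcm_value_names)
    add("glcm_mbb", NA_integer_, paste0("d=", d), v)
  for (w in ws) for (b in .lbp_bins) add("lbp", w, "p=8", b)
  for (w in ws) for (f in seq(0.1, 0.5, by = 0.1)) for (sg in 1:3)
    for (s in .gabor_stats)
      add("gabor", w, sprintf("f=%.1f,s=%d", f, sg), s)
  for (w in ws) for (pl in .haar_planes) for (s in c("mean_abs", "sd"))
    add("haar", w, pl, s)
  for (w in ws) for (i in 1:7) add("hu", w, paste0("i=", i), "median")
  zi <- zernike_indices(8L)
  for (w in ws) for (k in seq_len(nrow(zi)))
    add("zernike", w, sprintf("n=%d,m=%d", zi[k, "n"], zi[k, "m"]), "median")
  for (w in ws) add("hog", w, "", "mean")
  add("sobel", NA_integer_, "", "median_all")
  add("sobel", NA_integer_, "", "median_inner")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate feature specs for several image types
#'
#' @param image_types Character vector of image types (default all five).
#' @return Row-bound data.frame of [enumerate_feature_specs()] outputs.
#' @export
enumerate_all_specs <- function(image_types = .image_types) {
  do.call(rbind, lapply(image_types, enumerate_feature_specs))
}
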