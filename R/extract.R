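#' Default gray-level quantization ranges per image type
#'
#' GLCM extraction requires a fixed intensity range per image type. The
#' defaults anchor the parametric maps to their fitting search bounds
#' (ADCm/ADCk 0--3 um^2/ms, K 0--4, T2 1--300 ms) and T2w to
#' `[0, t2w_upper]`, where `t2w_upper` should be the top (99th-percentile)
#' landmark of the learned standard scale.
#'
#' @param t2w_upper Upper T2w quantization bound (a.u.).
#' @return Named list of length-2 ranges.
#' @export
default_quant_ranges <- function(t2w_upper = 1024) {
  list(ADCm = c(0, 3), ADCk = c(0, 3), K = c(0, 4), T2 = c(1, 300),
       T2w = c(0, t2w_upper))
}

# windowed sums for all top-left corners in tl (n x 2) given a SAT
.win_sums <- function(s, tl, w) {
  s[cbind(tl[, 1] + w, tl[, 2] + w)] - s[cbind(tl[, 1], tl[, 2] + w)] -
    s[cbind(tl[, 1] + w, tl[, 2])] + s[cbind(tl[, 1], tl[, 2])]
}

#' Extract the full texture-feature bank for one lesion
#'
#' Runs every descriptor of the bank on one lesion of one image volume and
#' returns the lesion-wise feature vector in the exact order of
#' [enumerate_feature_specs()]. All texture analysis is 2D per transverse
#' slice; sliding windows use only positions fully inside the lesion, with
#' the maximum-overlap fallback when no window fits (see
#' [window_positions()]). Windowed GLCM/Gabor/Haar/Hu/Zernike values are
#' aggregated by the pooled median over all valid positions of all slices
#' (or per-slice median then mean over slices with
#' `aggregation = "slice_mean"`); LBP features are the pooled pattern
#' frequency histogram; the HOG scalar is averaged over windows; MBB-GLCM
#' values are averaged over slices; Sobel medians and first-order
#' statistics are lesion-wide.
#'
#' @param image 3D numeric array (a parametric map or standardized T2w).
#' @param lesion_mask 3D logical array, same dimensions.
#' @param image_type One of `"T2w"`, `"ADCm"`, `"ADCk"`, `"K"`, `"T2"`.
#' @param quant_range Length-2 intensity range for 32-level quantization;
#'   default from [default_quant_ranges()].
#' @param aggregation `"pooled_median"` or `"slice_mean"`.
#' @return Named numeric vector (1281 or 1631 values).
#' @export
extract_lesion_features <- function(image, lesion_mask, image_type,
                                    quant_range = NULL,
                                    aggregation = c("pooled_median",
                                                    "slice_mean")) {
  aggregation <- match.arg(aggregation)
  if (!identical(dim(image), dim(lesion_mask))) stop("image/mask dimension mismatch")
  if (is.null(quant_range)) quant_range <- default_quant_ranges()[[image_type]]
  specs <- enumerate_feature_specs(image_type)
  ws <- window_grid(image_type)
  nz <- dim(image)[3]
  zbases <- lapply(ws, zernike_basis)
  names(zbases) <- as.character(ws)

  # per-slice accumulators: vals[[family key]][[slice]] = numeric vector
  med_vals <- list()     # families aggregated by median
  hog_vals <- lapply(as.character(ws), function(w) numeric(0))
  names(hog_vals) <- as.character(ws)
  lbp_codes <- hog_vals  # pooled LBP codes per window size
  mbb_rows <- list()     # per-slice MBB-GLCM 48-vectors
  push <- function(key, z, v) {
    if (is.null(med_vals[[key]])) med_vals[[key]] <<- vector("list", nz)
    med_vals[[key]][[z]] <<- c(med_vals[[key]][[z]], v)
  }

  lesion_slices <- which(apply(lesion_mask, 3, any))
  if (length(lesion_slices) == 0L) stop("empty lesion mask")

  for (z in lesion_slices) {
    sl <- image[, , z]
    mk <- lesion_mask[, , z]
    q <- quantize(sl, quant_range)
    gmaps <- gabor_response_maps(sl)
    gsats <- lapply(gmaps, function(g) {
      re <- Re(g)
      list(re = .sat(re), re2 = .sat(re^2), reabs = .sat(abs(re)),
           mod = .sat(Mod(g)))
    })
    hplanes <- haar_detail_planes(sl)
    hsats <- lapply(hplanes, function(p)
      list(x = .sat(p), x2 = .sat(p^2), xabs = .sat(abs(p))))

    for (w in ws) {
      wp <- window_positions(mk, w)
      tl <- wp$tl
      np <- nrow(tl)
      if (np == 0L) next
      wc <- as.character(w)
      n <- w * w
      # Gabor window statistics from summed-area tables
      for (g in names(gsats)) {
        sm <- .win_sums(gsats[[g]]$re, tl, w)
        sm2 <- .win_sums(gsats[[g]]$re2, tl, w)
        sabs <- .win_sums(gsats[[g]]$reabs, tl, w)
        smod <- .win_sums(gsats[[g]]$mod, tl, w)
        fs <- sub("f", "f=", sub("_s", ",s=", g))
        base <- paste0(image_type, ":gabor(", fs, "):w", w, ":")
        push(paste0(base, "mean_real"), z, sm / n)
        push(paste0(base, "var_real"), z, pmax(sm2 - sm^2 / n, 0) / (n - 1))
        push(paste0(base, "mean_abs_real"), z, sabs / n)
        push(paste0(base, "mean_magnitude"), z, smod / n)
      }
      # Haar window statistics from summed-area tables
      for (p in names(hsats)) {
        sx <- .win_sums(hsats[[p]]$x, tl, w)
        sx2 <- .win_sums(hsats[[p]]$x2, tl, w)
        sab <- .win_sums(hsats[[p]]$xabs, tl, w)
        base <- paste0(image_type, ":haar(", p, "):w", w, ":")
        push(paste0(base, "mean_abs"), z, sab / n)
        push(paste0(base, "sd"), z, sqrt(pmax(sx2 - sx^2 / n, 0) / (n - 1)))
      }
      # Zernike: stack patches and multiply against the precomputed basis
      zb <- zbases[[wc]]
      pmat <- matrix(0, n, np)
      for (i in seq_len(np))
        pmat[, i] <- as.vector(sl[tl[i, 1]:(tl[i, 1] + w - 1L),
                                  tl[i, 2]:(tl[i, 2] + w - 1L)])
      zmags <- Mod(t(zb$basis) %*% pmat[zb$inside, , drop = FALSE]) # 25 x np
      zi <- zb$indices
      for (k in seq_len(nrow(zi)))
        push(sprintf("%s:zernike(n=%d,m=%d):w%d:median", image_type,
                     zi[k, "n"], zi[k, "m"], w), z, zmags[k, ])
      # batched sliding-window GLCM
      dists <- .glcm_distances(w)
      gl <- .glcm_windowed_batch(q, tl, w, dists)
      for (di in seq_along(dists)) {
        base <- sprintf("%s:glcm(d=%d):w%d:", image_type, dists[di], w)
        for (v in seq_along(.glcm_value_names))
          push(paste0(base, .glcm_value_names[v]), z, gl[[di]][v, ])
      }
      # per-position loops: Hu, HOG, LBP center code
      ctr_off <- (w - 1L) %/% 2L
      humat <- matrix(0, 7L, np)
      hogv <- numeric(np)
      codes <- integer(np)
      for (i in seq_len(np)) {
        r0 <- tl[i, 1]; c0 <- tl[i, 2]
        patch <- sl[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
        humat[, i] <- hu_moments(patch)
        hogv[i] <- hog_feature(patch)
        codes[i] <- .lbp_code(patch, ctr_off + 1L, ctr_off + 1L, (w - 1) / 2)
      }
      for (j in 1:7)
        push(sprintf("%s:hu(i=%d):w%d:median", image_type, j, w), z, humat[j, ])
      hog_vals[[wc]] <- c(hog_vals[[wc]], hogv)
      lbp_codes[[wc]] <- c(lbp_codes[[wc]], codes)
    }
    # MBB-GLCM on this slice
    rr <- range(which(apply(mk, 1, any)))
    cr <- range(which(apply(mk, 2, any)))
    qb <- q[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    mb <- mk[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    mbb_rows[[length(mbb_rows) + 1L]] <-
      unlist(lapply(1:4, function(d) glcm_features(qb, d, mode = "mbb", mask = mb)))
  }

  out <- stats::setNames(rep(NA_real_, nrow(specs)), specs$name)
  lesion_vals <- image[lesion_mask]
  out[paste0(image_type, ":stats():w0:", .stat_names)] <- first_order_stats(lesion_vals)
  sob <- sobel_features(image, lesion_mask)
  out[paste0(image_type, ":sobel():w0:", c("median_all", "median_inner"))] <- sob
  mbb <- colMeans(do.call(rbind, mbb_rows))
  out[sprintf("%s:glcm_mbb(d=%d):w0:%s", image_type,
              rep(1:4, each = 12), rep(.glcm_value_names, 4))] <- mbb
  for (key in names(med_vals))
    out[key] <- aggregate_lesion(med_vals[[key]], aggregation)
  for (w in ws) {
    wc <- as.character(w)
    if (length(hog_vals[[wc]]) == 0L)
      stop("no valid positions for window ", w, " on any slice")
    out[sprintf("%s:hog():w%d:mean", image_type, w)] <- mean(hog_vals[[wc]])
    h <- tabulate(lbp_codes[[wc]] + 1L, nbins = 10L)
    out[sprintf("%s:lbp(p=8):w%d:%s", image_type, w, .lbp_bins)] <- h / sum(h)
  }
  if (anyNA(out)) stop("internal error: unfilled features: ",
                       paste(utils::head(names(out)[is.na(out)]), collapse = ", "))
  out
}

#' Extract features for every lesion of a phantom cohort
#'
#' Maps each lesion of each case through [extract_lesion_features()] for
#' the requested image types, sourcing the per-modality volumes from the
#' case: ground-truth parametric fields (`ADCk`, `K`, `T2`) or fitted maps
#' if supplied, and the (optionally standardized) T2w volume. When `ADCm`
#' is requested from ground truth, the `ADCk` field stands in for it (the
#' phantom has no separate monoexponential field); supply fitted maps via
#' `volumes` for a genuine ADCm.
#'
#' @param cohort A `phantom_cohort`.
#' @param image_types Subset of the five image types.
#' @param volumes Optional function `(case, image_type) -> 3D array`
#'   overriding the default source (ground-truth fields; raw T2w).
#' @param quant_ranges Named list of quantization ranges
#'   (default [default_quant_ranges()]).
#' @param aggregation Aggregation mode, see [extract_lesion_features()].
#' @return A [feature_table()].
#' @export
extract_cohort_features <- function(cohort,
                                    image_types = c("ADCk", "K", "T2", "T2w"),
                                    volumes = NULL,
                                    quant_ranges = default_quant_ranges(),
                                    aggregation = "pooled_median") {
  if (is.null(volumes)) {
    volumes <- function(case, type) {
      switch(type,
             ADCk = case$truth$ADCk, ADCm = case$truth$ADCk, K = case$truth$K,
             T2 = case$truth$T2, T2w = case$t2w)
    }
  }
  modality_of <- function(type) switch(type, T2w = "t2w", T2 = "t2", "dwi")
  rows <- list(); ids <- integer(0); labs <- numeric(0)
  for (case in cohort$cases) {
    for (li in seq_along(case$labels)) {
      feats <- unlist(lapply(image_types, function(tp) {
        mod <- modality_of(tp)
        extract_lesion_features(volumes(case, tp),
                                case$masks[[mod]]$lesions[[li]], tp,
                                quant_range = quant_ranges[[tp]],
                                aggregation = aggregation)
      }))
      rows[[length(rows) + 1L]] <- feats
      ids <- c(ids, case$patient_id)
      labs <- c(labs, case$labels[li])
    }
  }
  build_table(ids, labs, do.call(rbind, rows))
}
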