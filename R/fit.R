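#' Decay curve container
#'
#' One voxel's signal values over b values (DWI) or echo times (T2).
#'
#' @param abscissa b values (s/mm^2) or echo times (ms); strictly increasing.
#' @param signal Non-negative signal intensities (a.u.), same length.
#' @param kind `"dwi"` or `"t2"`.
#' @return Object of class `decay_curve`.
#' @export
decay_curve <- function(abscissa, signal, kind = c("dwi", "t2")) {
  kind <- match.arg(kind)
  if (length(abscissa) != length(signal)) stop("abscissa and signal lengths differ")
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  if (any(signal < 0)) stop("signal must be non-negative")
  structure(list(abscissa = as.numeric(abscissa), signal = as.numeric(signal),
                 kind = kind), class = "decay_curve")
}

.check_curve <- function(curve, kind, min_points) {
  if (!inherits(curve, "decay_curve")) stop("expected a decay_curve")
  if (curve$kind != kind) stop(sprintf("curve kind must be '%s'", kind))
  if (length(curve$signal) < min_points)
    stop(sprintf("need at least %d points", min_points))
  if (all(curve$signal == 0)) stop("degenerate curve: all-zero signal")
  # negative/zero intensities cannot arise from magnitude MRI, but clip
  # defensively so the signal-space objective stays well defined
  pmax(curve$signal, 1e-12)
}

.fit_result <- function(params, rss, n_starts, converged) {
  structure(list(params = params, rss = rss, n_starts_used = n_starts,
                 converged = converged), class = "fit_result")
}

# L-BFGS-B at a tight tolerance can end with an abnormal line-search code
# (52) when a start is already at the optimum and no step improves the
# objective; treat that as converged when the refined value did not regress
# past the start's profiled RSS.
.optim_converged <- function(o, start_rss) {
  o$convergence == 0 ||
    (o$convergence >= 51 && o$value <= start_rss + 1e-12 * (1 + start_rss))
}

# Final Levenberg-Marquardt polish of a candidate solution; the DWI
# objectives have narrow curved valleys at extreme (ADC, K) where
# quasi-Newton line searches stall, and damped least squares follows them.
.lm_polish <- function(par, resid_fn, lower, upper) {
  o <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(o)) return(NULL)
  list(par = o$par, value = sum(o$fvec^2), converged = o$info %in% 1:4)
}

# Profiled S0: for fixed decay shape e(x) the least-squares S0 is
# sum(s*e)/sum(e^2); returns c(S0, RSS).
.profile_s0 <- function(s, e) {
  s0 <- sum(s * e) / sum(e * e)
  c(s0, sum((s - s0 * e)^2))
}

#' Fit the monoexponential DWI model to one decay curve
#'
#' Least-squares fit of `S(b) = S0 exp(-b*ADCm/1000)` in signal space.
#' Multi-start: ADCm initializations on the grid 0.1--3.0 um^2/ms with step
#' 0.01 (coarsenable); every start is scored with the profiled closed-form
#' S0, and the best `n_refine` starts are polished by bounded quasi-Newton
#' (L-BFGS-B) on (S0, ADCm). The lowest-RSS solution is returned with ADCm
#' constrained to the search interval.
#'
#' @param curve A [decay_curve()] of kind `"dwi"` with >= 2 points.
#' @param grid_step ADCm start-grid step (um^2/ms), default 0.01.
#' @param n_refine Number of best starts polished by the optimizer.
#' @return A `fit_result` with `params = list(S0, ADCm)`, `rss`,
#'   `n_starts_used`, `converged`.
#' @export
fit_monoexp_dwi <- function(curve, grid_step = 0.01, n_refine = 10L) {
  s <- .check_curve(curve, "dwi", 2L)
  b <- curve$abscissa
  starts <- seq(0.1, 3.0, by = grid_step)
  prof <- vapply(starts, function(a) .profile_s0(s, exp(-b * a * 1e-3)),
                 numeric(2))
  ord <- order(prof[2, ])[seq_len(min(n_refine, length(starts)))]
  best <- NULL
  conv <- FALSE
  obj <- function(p) sum((s - p[1] * exp(-b * p[2] * 1e-3))^2)
  for (i in ord) {
    o <- stats::optim(c(max(prof[1, i], 1e-9), starts[i]), obj,
                      method = "L-BFGS-B",
                      lower = c(1e-12, 0.1), upper = c(Inf, 3.0),
                      control = list(factr = 10))
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- .optim_converged(o, prof[2, i])
    }
  }
  pol <- .lm_polish(best$par, function(p) s - p[1] * exp(-b * p[2] * 1e-3),
                    lower = c(1e-12, 0.1), upper = c(Inf, 3.0))
  if (!is.null(pol) && pol$value < best$value) {
    best <- pol
    conv <- pol$converged
  }
  .fit_result(list(S0 = best$par[1], ADCm = best$par[2]), best$value,
              length(starts), conv)
}

#' Fit the kurtosis DWI model to one decay curve
#'
#' Least-squares fit of `S(b) = S0 exp(-b*ADCk/1000 + (b*ADCk/1000)^2 K/6)`.
#' Multi-start over the (ADCk, K) grid ADCk = 0.01--3.0 step 0.1,
#' K = 0.0001--4.0 step 0.2 (coarsenable); starts are scored with profiled
#' S0 and the best `n_refine` polished by L-BFGS-B with K constrained to
#' [0, 4] and ADCk to [0.01, 3].
#'
#' @param curve A [decay_curve()] of kind `"dwi"` with >= 3 points.
#' @param adc_step,k_step Start-grid steps (defaults 0.1 and 0.2).
#' @param n_refine Number of best starts polished by the optimizer.
#' @return A `fit_result` with `params = list(S0, ADCk, K)`.
#' @export
fit_kurtosis_dwi <- function(curve, adc_step = 0.1, k_step = 0.2,
                             n_refine = 10L) {
  s <- .check_curve(curve, "dwi", 3L)
  b <- curve$abscissa
  adc_starts <- seq(0.01, 3.0, by = adc_step)
  k_starts <- seq(0.0001, 4.0, by = k_step)
  grid <- expand.grid(adc = adc_starts, k = k_starts)
  rssg <- mapply(function(a, k) {
    bd <- b * a * 1e-3
    .profile_s0(s, exp(-bd + bd^2 * k / 6))[2]
  }, grid$adc, grid$k)
  ord <- order(rssg)[seq_len(min(n_refine, nrow(grid)))]
  obj <- function(p) {
    bd <- b * p[2] * 1e-3
    sum((s - p[1] * exp(-bd + bd^2 * p[3] / 6))^2)
  }
  resid_fn <- function(p) {
    bd <- b * p[2] * 1e-3
    s - p[1] * exp(-bd + bd^2 * p[3] / 6)
  }
  lo <- c(1e-12, 0.01, 0); hi <- c(Inf, 3.0, 4.0)
  # extra start at the K = 0 boundary from a fine monoexponential scan: the
  # kurtosis model nests the monoexponential one, and this start keeps the
  # fitted RSS from ever exceeding the monoexponential fit's
  mono_scan <- vapply(seq(0.1, 3.0, by = 0.01), function(a)
    .profile_s0(s, exp(-b * a * 1e-3)), numeric(2))
  mi <- which.min(mono_scan[2, ])
  starts <- c(lapply(ord, function(i) {
    bd <- b * grid$adc[i] * 1e-3
    c(max(.profile_s0(s, exp(-bd + bd^2 * grid$k[i] / 6))[1], 1e-9),
      grid$adc[i], grid$k[i])
  }), list(c(max(mono_scan[1, mi], 1e-9), seq(0.1, 3.0, by = 0.01)[mi], 0)))
  start_rss <- c(rssg[ord], mono_scan[2, mi])
  best <- NULL
  k0_cand <- NULL
  conv <- FALSE
  for (i in seq_along(starts)) {
    o <- stats::optim(starts[[i]], obj, method = "L-BFGS-B",
                      lower = lo, upper = hi, control = list(factr = 10))
    if (i == length(starts)) k0_cand <- o
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- .optim_converged(o, start_rss[i])
    }
  }
  # polish both the overall best and the K = 0 boundary candidate, so the
  # returned RSS can never exceed the (equally polished) monoexponential fit
  for (cand in list(best, k0_cand)) {
    pol <- .lm_polish(cand$par, resid_fn, lo, hi)
    if (!is.null(pol) && pol$value < best$value) {
      best <- pol
      conv <- pol$converged
    }
  }
  .fit_result(list(S0 = best$par[1], ADCk = best$par[2], K = best$par[3]),
              best$value, nrow(grid), conv)
}

#' Fit the two-parameter T2 relaxometry model to one decay curve
#'
#' Damped least squares (Levenberg--Marquardt, via minpack.lm) fit of
#' `S(TE) = S0 exp(-TE/T2)` from 7 starts T2 = 0, 50, ..., 300 ms (the 0 ms
#' start is clamped to the lower bound); T2 is constrained to [1, 300] ms.
#'
#' @param curve A [decay_curve()] of kind `"t2"` with >= 2 points.
#' @return A `fit_result` with `params = list(S0, T2)`.
#' @export
fit_t2 <- function(curve) {
  s <- .check_curve(curve, "t2", 2L)
  te <- curve$abscissa
  starts <- pmax(seq(0, 300, by = 50), 1)
  resid_fn <- function(p) s - p[1] * exp(-te / p[2])
  best <- NULL
  conv <- FALSE
  for (t2s in starts) {
    s0s <- max(s[1] * exp(te[1] / t2s), 1e-9) # back-extrapolate first echo
    o <- tryCatch(
      minpack.lm::nls.lm(par = c(s0s, t2s), fn = resid_fn,
                         lower = c(1e-12, 1), upper = c(Inf, 300),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(o)) next
    rss <- sum(o$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = o$par, rss = rss)
      conv <- o$info %in% 1:4
    }
  }
  if (is.null(best)) {
    return(.fit_result(list(S0 = NA_real_, T2 = NA_real_), Inf,
                       length(starts), FALSE))
  }
  .fit_result(list(S0 = best$par[1], T2 = min(max(best$par[2], 1), 300)),
              best$rss, length(starts), conv)
}

#' Voxel-wise fitting of a 4D series
#'
#' Applies the chosen single-voxel fitter to every in-mask voxel of a 4D
#' series and assembles 3D parametric maps. Out-of-mask voxels are NaN.
#' A convergence QC map (1 converged / 0 not, NaN outside) is included.
#'
#' @param series_4d 4D array, 4th dimension = b values or echo times.
#' @param mask 3D logical array aligned to the first three dimensions.
#' @param model `"mono"`, `"kurtosis"`, or `"t2"`.
#' @param abscissa b values (s/mm^2) or echo times (ms) of the 4th
#'   dimension.
#' @param ... Passed to the single-voxel fitter (e.g. `grid_step`,
#'   `n_refine` to coarsen the start grid).
#' @return Named list of 3D maps: fitted parameters (`ADCm` or
#'   `ADCk` + `K` or `T2`, plus `S0`), `rss`, and `converged`.
#' @export
fit_volume <- function(series_4d, mask, model = c("mono", "kurtosis", "t2"),
                       abscissa, ...) {
  model <- match.arg(model)
  d <- dim(series_4d)
  if (length(d) != 4L) stop("series_4d must be 4D")
  if (d[4] != length(abscissa)) stop("4th dimension does not match abscissa length")
  if (!identical(dim(mask), d[1:3])) stop("mask not aligned to series grid")
  kind <- if (model == "t2") "t2" else "dwi"
  pnames <- switch(model, mono = c("S0", "ADCm"), kurtosis = c("S0", "ADCk", "K"),
                   t2 = c("S0", "T2"))
  maps <- lapply(c(pnames, "rss", "converged"),
                 function(nm) array(NaN, dim = d[1:3]))
  names(maps) <- c(pnames, "rss", "converged")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(maps)
  mat <- matrix(series_4d, nrow = prod(d[1:3]), ncol = d[4])
  flat <- which(mask)
  for (r in seq_along(flat)) {
    sig <- mat[flat[r], ]
    curve <- decay_curve(abscissa, pmax(sig, 0), kind = kind)
    fit <- switch(model,
                  mono = fit_monoexp_dwi(curve, ...),
                  kurtosis = fit_kurtosis_dwi(curve, ...),
                  t2 = fit_t2(curve))
    for (nm in pnames) maps[[nm]][flat[r]] <- fit$params[[nm]]
    maps$rss[flat[r]] <- fit$rss
    maps$converged[flat[r]] <- as.numeric(fit$converged)
  }
  maps
}
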