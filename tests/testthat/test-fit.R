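p12 <- acquisition_protocol()

# independent brute-force 2-D grid oracle over (S0, ADCm): expands
# rss(s0, a) = sum(s^2) - 2 s0 sum(s e) + s0^2 sum(e^2) over the full grid
oracle_mono <- function(curve, adc_grid, s0_grid) {
  E <- exp(-outer(curve$abscissa, adc_grid) * 1e-3)
  se <- as.numeric(crossprod(E, curve$signal))
  ee <- colSums(E^2)
  rss <- sum(curve$signal^2) - 2 * outer(se, s0_grid) +
    outer(ee, s0_grid^2)
  i <- arrayInd(which.min(rss), dim(rss))
  list(rss = min(rss), s0 = s0_grid[i[2]], adc = adc_grid[i[1]])
}

test_that("noise-free monoexponential curves are recovered exactly", {
  for (adcm in c(0.3, 1.0, 2.2)) for (s0 in c(1, 500)) {
    cv <- decay_curve(p12$b_values, kurtosis_signal(p12$b_values, s0, adcm, 0), "dwi")
    f <- fit_monoexp_dwi(cv, grid_step = 0.1)
    expect_lt(abs(f$params$ADCm - adcm), 1e-4)
    expect_lt(f$rss, 1e-10)
    expect_true(f$converged)
  }
})

test_that("noise-free kurtosis curves are recovered and the model nests", {
  cv <- simulate_dwi_signal(list(S0 = 1, ADCk = 0.9, K = 1.2), p12, 0)
  f <- fit_kurtosis_dwi(cv)
  expect_lt(abs(f$params$ADCk - 0.9), 1e-3)
  expect_lt(abs(f$params$K - 1.2), 1e-3)
  # K = 0 curve: kurtosis fit finds K ~ 0 and ADCk ~ ADCm
  cv0 <- simulate_dwi_signal(list(S0 = 1, ADCk = 1.0, K = 0), p12, 0)
  fk <- fit_kurtosis_dwi(cv0)
  fm <- fit_monoexp_dwi(cv0)
  expect_lt(fk$params$K, 1e-3)
  expect_lt(abs(fk$params$ADCk - fm$params$ADCm), 1e-3)
})

test_that("kurtosis RSS never exceeds monoexponential RSS (nesting)", {
  set.seed(21)
  # unit-amplitude curves: the 1e-9 slack is meaningful at S0 = 1, and both
  # fits are scale equivariant
  for (i in 1:10) {
    cv <- simulate_dwi_signal(list(S0 = 1, ADCk = runif(1, 0.4, 2),
                                   K = runif(1, 0, 2)), p12,
                              noise_sigma = 0.0375)
    fm <- fit_monoexp_dwi(cv, grid_step = 0.1)
    fk <- fit_kurtosis_dwi(cv)
    expect_lte(fk$rss, fm$rss + 1e-9)
  }
})

test_that("fits are scale equivariant", {
  set.seed(22)
  cv <- simulate_dwi_signal(list(S0 = 100, ADCk = 1.1, K = 0.8), p12, 5)
  f1 <- fit_kurtosis_dwi(cv)
  cv2 <- decay_curve(cv$abscissa, cv$signal * 7.5, "dwi")
  f2 <- fit_kurtosis_dwi(cv2)
  expect_equal(f2$params$S0 / f1$params$S0, 7.5, tolerance = 1e-6)
  expect_equal(f2$params$ADCk, f1$params$ADCk, tolerance = 1e-6)
  expect_equal(f2$params$K, f1$params$K, tolerance = 1e-6)
  tc <- simulate_t2_signal(list(S0 = 50, T2 = 90), noise_sigma = 1)
  g1 <- fit_t2(tc)
  g2 <- fit_t2(decay_curve(tc$abscissa, tc$signal * 3, "t2"))
  expect_equal(g2$params$T2, g1$params$T2, tolerance = 1e-6)
})

test_that("constant DWI signal drives ADCm to the lower search bound", {
  cv <- decay_curve(p12$b_values, rep(5, 12), "dwi")
  f <- fit_monoexp_dwi(cv)
  orc <- oracle_mono(cv, seq(0.1, 3, by = 1e-4), seq(4, 6, by = 0.01))
  expect_equal(f$params$ADCm, 0.1, tolerance = 1e-4)
  expect_equal(orc$adc, 0.1, tolerance = 1e-4)
  expect_lte(f$rss, orc$rss + 1e-9)
})

test_that("T2 fitting recovers noise-free values and clamps out-of-bound truth", {
  tes <- c(20, 40, 60, 80, 100)
  f <- fit_t2(decay_curve(tes, t2_signal(tes, 1, 100), "t2"))
  expect_lt(abs(f$params$T2 - 100), 0.1)
  f5 <- fit_t2(decay_curve(tes, t2_signal(tes, 1, 500), "t2"))
  expect_equal(f5$params$T2, 300)
  expect_error(fit_t2(decay_curve(tes, rep(0, 5), "t2")), "all-zero")
})

test_that("noisy fits match brute-force grid oracles within grid resolution", {
  set.seed(23)
  for (i in 1:5) {
    cv <- simulate_dwi_signal(list(S0 = 300, ADCk = runif(1, 0.5, 2), K = 0),
                              p12, noise_sigma = 10)
    f <- fit_monoexp_dwi(cv)
    s0g <- seq(0.8, 1.2, by = 0.01) * max(cv$signal)
    orc <- oracle_mono(cv, seq(0.1, 3, by = 0.01), s0g)
    expect_lte(f$rss, orc$rss + 1e-9)
    expect_lt(abs(f$params$ADCm - orc$adc), 0.01 + 1e-9)
  }
})

test_that("fit_volume maps every in-mask voxel and leaves the rest NaN", {
  dm <- c(4, 4, 2)
  adc <- array(runif(prod(dm), 0.6, 1.8), dm)
  s0 <- array(100, dm)
  b <- p12$b_values
  series <- array(0, c(dm, length(b)))
  for (k in seq_along(b)) series[, , , k] <- s0 * exp(-b[k] * adc * 1e-3)
  mask <- array(FALSE, dm); mask[2:3, 2:3, 1] <- TRUE
  maps <- fit_volume(series, mask, "mono", b, grid_step = 0.1)
  expect_equal(maps$ADCm[mask], adc[mask], tolerance = 1e-3)
  expect_true(all(is.nan(maps$ADCm[!mask])))
  expect_true(all(maps$converged[mask] == 1))
  # empty mask: all-sentinel maps, no error
  empty <- fit_volume(series, array(FALSE, dm), "mono", b)
  expect_true(all(is.nan(empty$ADCm)))
  expect_error(fit_volume(series, array(FALSE, c(5, 4, 2)), "mono", b), "aligned")
  expect_error(fit_volume(series, mask, "mono", b[-1]), "abscissa")
})
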