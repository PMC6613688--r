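test_that("first-order statistics match closed-form percentiles", {
  f <- first_order_stats(1:100)
  expect_length(f, 18)
  expect_equal(unname(f["p25"]), 25.75) # linear-interpolation convention
  expect_equal(unname(f["range"]), 99)
  expect_equal(unname(f["p50"]), 50.5)
  expect_equal(unname(f["mean"]), 50.5)
})

test_that("constant input uses the degenerate conventions", {
  f <- first_order_stats(rep(3, 10))
  expect_equal(unname(f[c("sd", "range", "skewness", "kurtosis")]), rep(0, 4))
  expect_equal(unname(f["mean"]), 3)
  expect_error(first_order_stats(numeric(0)), "empty")
  expect_length(first_order_stats(5), 18)
})

test_that("skewness and kurtosis match their moment definitions", {
  set.seed(51)
  v <- rexp(5000)
  f <- first_order_stats(v)
  z <- v - mean(v)
  expect_equal(unname(f["skewness"]), mean(z^3) / mean(z^2)^1.5)
  expect_equal(unname(f["kurtosis"]), mean(z^4) / mean(z^2)^2 - 3)
})

test_that("a 9x9 square lesion admits 7x7 positions for a 3-window", {
  mask <- matrix(FALSE, 15, 15)
  mask[4:12, 4:12] <- TRUE
  wp <- window_positions(mask, 3)
  expect_equal(nrow(wp$tl), 49)
  expect_false(wp$fallback)
  # every returned window is fully inside the lesion
  for (i in seq_len(nrow(wp$tl)))
    expect_true(all(mask[wp$tl[i, 1]:(wp$tl[i, 1] + 2), wp$tl[i, 2]:(wp$tl[i, 2] + 2)]))
})

test_that("the maximum-overlap fallback engages for windows larger than the lesion", {
  mask <- matrix(FALSE, 15, 15)
  mask[7:9, 7:9] <- TRUE # 3x3 lesion
  wp <- window_positions(mask, 7)
  expect_true(wp$fallback)
  expect_gt(nrow(wp$tl), 0)
  # all returned positions cover the whole lesion (max overlap = 9)
  for (i in seq_len(nrow(wp$tl))) {
    sub <- mask[wp$tl[i, 1]:(wp$tl[i, 1] + 6), wp$tl[i, 2]:(wp$tl[i, 2] + 6)]
    expect_equal(sum(sub), 9)
  }
})

test_that("valid positions on an L-shaped lesion match a brute-force oracle", {
  mask <- matrix(FALSE, 14, 14)
  mask[3:12, 3:7] <- TRUE # arms wide enough that both window sizes fit
  mask[8:12, 3:12] <- TRUE
  for (w in c(3, 5)) {
    wp <- window_positions(mask, w)
    brute <- list()
    for (r in 1:(15 - w)) for (cc in 1:(15 - w)) {
      if (all(mask[r:(r + w - 1), cc:(cc + w - 1)]))
        brute[[length(brute) + 1]] <- c(r, cc)
    }
    brute <- do.call(rbind, brute)
    expect_equal(wp$tl[order(wp$tl[, 1], wp$tl[, 2]), ],
                 brute[order(brute[, 1], brute[, 2]), ])
  }
})

test_that("lesion aggregation modes follow their definitions", {
  expect_equal(aggregate_lesion(list(c(1, 2), c(3, 4))), 2.5)
  expect_equal(aggregate_lesion(list(c(1, 2, 3), c(10)), mode = "slice_mean"), 6)
  # the two modes genuinely differ on asymmetric maps
  vals <- list(c(0, 0, 0, 10), c(5))
  expect_equal(aggregate_lesion(vals), 0)
  expect_equal(aggregate_lesion(vals, mode = "slice_mean"), 2.5)
  expect_equal(aggregate_lesion(list(numeric(0), 7)), 7)
  expect_error(aggregate_lesion(list(numeric(0))), "no valid positions")
})
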