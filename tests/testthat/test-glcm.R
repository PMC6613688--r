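test_that("quantization follows the floor/clip contract", {
  expect_equal(unique(as.vector(quantize(matrix(0.5, 4, 4), c(0, 1)))), 16L)
  expect_equal(quantize(matrix(c(0, 1), 1, 2), c(0, 1))[1, ], c(0L, 31L))
  expect_equal(quantize(matrix(c(-5, 99), 1, 2), c(0, 1))[1, ], c(0L, 31L))
  ramp <- matrix(seq(0, 1, length.out = 3200), 40, 80)
  counts <- tabulate(quantize(ramp, c(0, 1)) + 1L, 32)
  expect_lte(diff(range(counts)), 1)
  expect_error(quantize(matrix(1), c(2, 1)), "inverted")
})

test_that("constant patches give the Haralick identities", {
  q <- matrix(7L, 6, 6)
  f <- glcm_features(q, 1)
  expect_equal(unname(f["contrast_mean"]), 0)
  expect_equal(unname(f["homogeneity_mean"]), 1)
  expect_equal(unname(f["energy_mean"]), 1)
  expect_equal(unname(f["correlation_mean"]), 1)
  expect_true(all(f[grep("_range", names(f))] == 0))
})

test_that("a binary checkerboard at d=1 has horizontal contrast 1 and correlation -1", {
  cb <- outer(1:4, 1:4, function(i, j) as.integer((i + j) %% 2))
  cc <- mpradiomics:::.cooc_counts(cb, 0L, 1L, 2L) # horizontal orientation only
  expect_equal(sum(cc), 24) # 12 pairs, both directions
  h <- mpradiomics:::.haralick6(cc / sum(cc), mpradiomics:::.haralick_consts(c(0, 1)))
  expect_equal(unname(h["contrast"]), 1)
  expect_equal(unname(h["correlation"]), -1)
})

test_that("windowed GLCM equals the literal pair-enumeration oracle", {
  for (seed in 1:4) {
    q <- quantize(random_patch(5, seed), c(0, 1))
    for (d in 1:2) {
      expect_equal(unname(glcm_features(q, d)), oracle_glcm(q, d),
                   tolerance = 1e-12, label = sprintf("seed %d d %d", seed, d))
    }
  }
})

test_that("MBB GLCM ignores non-lesion voxels, matching the masked oracle", {
  set.seed(31)
  q <- quantize(matrix(runif(49), 7, 7), c(0, 1))
  mask <- matrix(FALSE, 7, 7)
  mask[2:6, 2:5] <- TRUE
  mask[3, 3] <- FALSE # a hole
  got <- glcm_features(q, 1, mode = "mbb", mask = mask)
  expect_equal(unname(got), oracle_glcm(q, 1, mask = mask), tolerance = 1e-12)
  expect_error(glcm_features(q, 1, mode = "mbb"), "mask")
})

test_that("distances with no valid pairs yield all-zero features", {
  q <- matrix(c(0L, 5L, 9L, 2L, 7L, 1L, 4L, 3L, 8L), 3, 3)
  expect_true(all(glcm_features(q, 3) == 0)) # d = 3 on a 3x3 window
})

test_that("the batched sliding-window path agrees with per-patch evaluation", {
  set.seed(32)
  sl <- matrix(runif(26 * 24), 26, 24)
  q <- quantize(sl, c(0, 1))
  tl <- cbind(sample(1:12, 8), sample(1:10, 8))
  for (w in c(3, 7)) {
    dists <- mpradiomics:::.glcm_distances(w)
    batch <- mpradiomics:::.glcm_windowed_batch(q, tl, w, dists)
    for (i in seq_len(nrow(tl))) for (d in dists) {
      ref <- glcm_features(q[tl[i, 1]:(tl[i, 1] + w - 1L),
                             tl[i, 2]:(tl[i, 2] + w - 1L)], d)
      expect_equal(unname(batch[[as.character(d)]][, i]), unname(ref),
                   tolerance = 1e-9)
    }
  }
})

test_that("GLCM orientation means are invariant under 90-degree patch rotation", {
  set.seed(33)
  q <- quantize(matrix(runif(81), 9, 9), c(0, 1))
  rot <- t(q)[nrow(q):1, ] # 90-degree rotation
  f1 <- glcm_features(q, 1)
  f2 <- glcm_features(rot, 1)
  means <- grep("_mean", names(f1))
  expect_equal(f1[means], f2[means], tolerance = 1e-10)
})
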