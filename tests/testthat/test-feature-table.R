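dummy_full_table <- function(n = 4, seed = 71) {
  set.seed(seed)
  nm <- enumerate_all_specs()$name
  x <- matrix(rnorm(n * length(nm)), n,
              dimnames = list(NULL, nm))
  feature_table(seq_len(n), c(-1, 1, 1, 1)[seq_len(n)], x)
}

test_that("tables validate their invariants on construction", {
  t <- dummy_full_table()
  expect_equal(ncol(t$features), 7105)
  expect_error(feature_table(1:2, c(0, 1), matrix(1:4, 2,
               dimnames = list(NULL, c("a", "b")))), "labels")
  expect_error(feature_table(1:3, c(-1, 1), matrix(1:4, 2,
               dimnames = list(NULL, c("a", "b")))), "ragged")
  expect_error(feature_table(1:2, c(-1, 1), matrix(c(1, NA, 3, 4), 2,
               dimnames = list(NULL, c("a", "b")))), "finite")
  expect_error(build_table(1:2, c(-1, 1),
               list(c(a = 1, b = 2), c(a = 1, z = 2))), "mismatched")
})

test_that("image-type subsets have the documented column counts", {
  t <- dummy_full_table()
  expect_equal(ncol(subset_by_image_types(t, c("ADCm", "K", "T2w"))$features), 4193)
  expect_equal(ncol(subset_by_image_types(t, c("T2", "T2w"))$features), 3262)
  expect_equal(ncol(subset_by_image_types(t, "ADCk")$features), 1281)
  full <- subset_by_image_types(t, c("T2w", "ADCm", "ADCk", "K", "T2"))
  expect_identical(full$features, t$features)
  expect_error(subset_by_image_types(t, "DCE"), "unknown")
})

test_that("normalization gives zero-mean unit-variance columns and maps constants to 0", {
  set.seed(72)
  x <- cbind(a = rnorm(10, 5, 3), b = runif(10), c = rep(2, 10))
  t <- feature_table(1:10, c(rep(-1, 3), rep(1, 7)), x)
  z <- normalize_features(t)
  expect_equal(unname(colMeans(z$features)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z$features[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_true(all(z$features[, "c"] == 0))
})

test_that("training-row normalization transforms held-out rows without leakage", {
  x <- cbind(f1 = c(0, 2, 4, 100), f2 = c(1, 1, 3, 50))
  t <- feature_table(1:4, c(-1, -1, 1, 1), x)
  z <- normalize_features(t, reference_rows = 1:3)
  # hand computation: f1 ref mean 2, sd 2; f2 ref mean 5/3, sd sqrt(4/3)
  expect_equal(unname(z$features[, "f1"]), (x[, "f1"] - 2) / 2)
  expect_equal(unname(z$features[, "f2"]),
               (x[, "f2"] - 5 / 3) / sqrt(4 / 3), tolerance = 1e-12)
})

test_that("CSV round trip preserves layout, labels and full precision", {
  set.seed(73)
  t <- feature_table(c(101, 101, 205, 310),
                     c(-1, 1, 1, -1),
                     matrix(rnorm(4 * 6) * 1e-7, 4,
                            dimnames = list(NULL, paste0("ADCm:stats():w0:f", 1:6))))
  path <- tempfile(fileext = ".csv")
  write_feature_csv(t, path)
  back <- read_feature_csv(path)
  expect_identical(back$label, t$label)
  expect_equal(back$patient_id, t$patient_id)
  expect_identical(back$features, t$features) # bit-exact round trip
  expect_identical(back$image_type, t$image_type)
})

test_that("malformed CSV inputs raise parse errors", {
  p <- tempfile(fileext = ".csv")
  writeLines(character(0), p)
  expect_error(read_feature_csv(p))
  writeLines(c("id,label,f1", "1,0,2.5"), p)
  expect_error(read_feature_csv(p), "-1")
})
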