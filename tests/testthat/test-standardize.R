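make_img <- function(seed, scale = 1) {
  set.seed(seed)
  img <- array(rgamma(20 * 20 * 4, shape = 4, rate = 1 / 50), c(20, 20, 4)) * scale
  mask <- array(FALSE, c(20, 20, 4)); mask[4:17, 4:17, ] <- TRUE
  list(img = img, mask = mask)
}

test_that("a single image defines its own standard scale", {
  a <- make_img(1)
  sc <- learn_standard_scale(list(a$img), list(a$mask))
  expect_equal(unname(sc$standard),
               unname(quantile(a$img[a$mask], landmark_positions(), type = 7)))
})

test_that("scaling an image by 2 puts the standard scale at 1.5x the smaller", {
  a <- make_img(2)
  sc <- learn_standard_scale(list(a$img, a$img * 2), list(a$mask, a$mask))
  own <- quantile(a$img[a$mask], landmark_positions(), type = 7)
  expect_equal(unname(sc$standard), unname(1.5 * own), tolerance = 1e-12)
})

test_that("standardization is idempotent and preserves monotone order", {
  a <- make_img(3)
  sc <- learn_standard_scale(list(a$img, a$img * 1.7), list(a$mask, a$mask))
  s1 <- standardize_image(a$img, a$mask, sc)
  s2 <- standardize_image(s1, a$mask, sc)
  expect_equal(s2, s1, tolerance = 1e-6)
  # rank order inside the mask is preserved
  v <- a$img[a$mask]; w <- s1[a$mask]
  ord <- order(v)
  expect_true(all(diff(w[ord]) >= -1e-9))
  # a monotone ramp stays monotone
  ramp <- array(seq(0, 1000, length.out = prod(dim(a$img))), dim(a$img))
  sr <- standardize_image(ramp, a$mask, sc)
  expect_true(all(diff(as.vector(sr)) >= -1e-9))
})

test_that("an image at 3x the standard scale maps back onto the standard deciles", {
  a <- make_img(4)
  sc <- learn_standard_scale(list(a$img), list(a$mask))
  out <- standardize_image(a$img * 3, a$mask, sc)
  got <- quantile(out[a$mask], landmark_positions(), type = 7)
  expect_equal(unname(got), unname(sc$standard), tolerance = 1e-6)
})

test_that("degenerate inputs error out", {
  a <- make_img(5)
  sc <- learn_standard_scale(list(a$img), list(a$mask))
  expect_error(standardize_image(array(7, dim(a$img)), a$mask, sc), "constant")
  expect_error(learn_standard_scale(list(a$img), list(array(FALSE, dim(a$img)))),
               "empty")
})

test_that("standardization strictly reduces cross-patient landmark dispersion", {
  coh <- test_cohort() # drift_amplitude 0.3
  imgs <- lapply(coh$cases, `[[`, "t2w")
  masks <- lapply(coh$cases, function(cs) cs$masks$t2w$prostate)
  sc <- learn_standard_scale(imgs, masks)
  std <- mapply(standardize_image, imgs, masks,
                MoreArgs = list(standard_scale = sc), SIMPLIFY = FALSE)
  lm_pre <- t(mapply(function(im, mk)
    quantile(im[mk], landmark_positions(), type = 7), imgs, masks))
  lm_post <- t(mapply(function(im, mk)
    quantile(im[mk], landmark_positions(), type = 7), std, masks))
  cv <- function(m) apply(m, 2, sd) / colMeans(m)
  # per-landmark coefficient of variation across patients must shrink
  expect_true(all(cv(lm_post) < cv(lm_pre)))
})

test_that("standard scales survive a JSON round trip", {
  a <- make_img(6)
  sc <- learn_standard_scale(list(a$img), list(a$mask))
  path <- tempfile(fileext = ".json")
  write_standard_scale(sc, path)
  back <- read_standard_scale(path)
  expect_equal(back$standard, unname(sc$standard), tolerance = 1e-12)
  expect_equal(back$positions, landmark_positions())
})
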