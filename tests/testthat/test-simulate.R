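test_that("kurtosis signal matches closed forms and reduces to monoexponential", {
  expect_equal(kurtosis_signal(1000, 1, 1.0, 0), exp(-1))
  expect_equal(kurtosis_signal(2000, 1, 1.0, 1.0), exp(-2 + 4 / 6))
  b <- acquisition_protocol()$b_values
  expect_equal(kurtosis_signal(b, 2, 1.3, 0), 2 * exp(-b * 1.3e-3))
})

test_that("noise-free simulated curves match an independent term-by-term evaluation", {
  p <- acquisition_protocol()
  cv <- simulate_dwi_signal(list(S0 = 500, ADCk = 0.8, K = 1.5), p, noise_sigma = 0)
  # second implementation: accumulate the exponent from its two terms
  oracle <- vapply(p$b_values, function(b) {
    term1 <- -(b / 1000) * 0.8
    term2 <- (1 / 6) * (b / 1000)^2 * 0.8^2 * 1.5
    500 * exp(term1 + term2)
  }, numeric(1))
  expect_equal(cv$signal, oracle, tolerance = 1e-12)
  expect_s3_class(cv, "decay_curve")
  expect_identical(cv$kind, "dwi")

  tes <- c(20, 40, 60, 80, 100)
  tc <- simulate_t2_signal(list(S0 = 100, T2 = 80), tes, noise_sigma = 0)
  expect_equal(tc$signal, vapply(tes, function(te) 100 * 2^(-te / (80 * log(2))),
                                 numeric(1)), tolerance = 1e-12)
  expect_equal(t2_signal(100, 1, 100), exp(-1))
  expect_equal(t2_signal(0, 2, 50), 2)
})

test_that("parameter preconditions are enforced", {
  p <- acquisition_protocol()
  expect_error(simulate_dwi_signal(list(S0 = 0, ADCk = 1), p), "S0")
  expect_error(simulate_dwi_signal(list(S0 = 1, ADCk = -1), p), "ADCk")
  expect_error(simulate_t2_signal(list(S0 = 1, T2 = 500)), "T2")
  expect_error(simulate_t2_signal(list(S0 = 1, T2 = 0.5)), "T2")
  expect_error(acquisition_protocol(b_values = c(100, 200)), "first value 0")
  expect_error(tissue_class_model(2, 1, 0, 1, 0, 1, 0, 1, 0), "label")
})

test_that("Rician noise is unbiased at high SNR and exact at sigma zero", {
  expect_identical(rician(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(11)
  s <- 100; sigma <- 2 # SNR 50
  draws <- rician(rep(s, 2e4), sigma)
  expect_lt(abs(mean(draws) - s) / s, 0.02)
  expect_gt(sd(draws), 0)
})

test_that("textured fields have the requested mean, spread and determinism", {
  f0 <- render_textured_field(c(20, 20, 5), mean = 10, variance_scale = 0)
  expect_true(all(f0 == 10))
  set.seed(3)
  f <- render_textured_field(c(30, 30, 12), mean = 50, variance_scale = 0.1,
                             correlation_length = 0)
  expect_equal(sd(f), 0.1 * 50, tolerance = 0.05)
  expect_equal(mean(f), 50, tolerance = 0.02)
  set.seed(9); a <- render_textured_field(c(10, 10), 5, 0.2, 1.5)
  set.seed(9); b <- render_textured_field(c(10, 10), 5, 0.2, 1.5)
  expect_identical(a, b)
  # smoothing approximately preserves the marginal sd away from edges
  set.seed(4)
  g <- render_textured_field(c(80, 80), mean = 100, variance_scale = 0.2,
                             correlation_length = 2)
  core <- g[20:60, 20:60]
  expect_equal(sd(core), 20, tolerance = 0.2)
})

test_that("cohorts are reproducible and respect the class ratio and geometry", {
  a <- generate_cohort(3, protocol = small_protocol(), seed = 7,
                       lesion_counts = c(1, 2, 1))
  b <- generate_cohort(3, protocol = small_protocol(), seed = 7,
                       lesion_counts = c(1, 2, 1))
  expect_identical(a, b)
  c2 <- generate_cohort(3, protocol = small_protocol(), seed = 8,
                        lesion_counts = c(1, 2, 1))
  expect_false(identical(a$cases[[1]]$t2w, c2$cases[[1]]$t2w))
  expect_true(all(a$labels %in% c(-1, 1)))
  for (cs in a$cases) {
    for (mod in c("dwi", "t2", "t2w")) {
      for (lm in cs$masks[[mod]]$lesions) {
        expect_true(all(cs$masks[[mod]]$prostate[lm])) # lesion inside prostate
        expect_gt(sum(lm), 0)
      }
    }
  }
})

test_that("a 100-lesion cohort at the default ratio has 20 low and 80 high labels", {
  counts <- rep(c(1, 2, 3), c(29, 28, 5)) # 29+56+15 = 100 lesions
  coh <- generate_cohort(62, protocol = small_protocol(), seed = 5,
                         lesion_counts = counts, drift_amplitude = 0)
  expect_identical(sum(coh$labels == -1), 20L)
  expect_identical(sum(coh$labels == 1), 80L)
  expect_length(coh$cases, 62)
})

test_that("NSA-averaged noise-free DWI volumes follow the kurtosis decay exactly", {
  coh <- generate_cohort(2, protocol = small_protocol(), seed = 13,
                         lesion_counts = c(1, 1), dwi_sigma = 0, t2_sigma = 0,
                         t2w_sigma = 0, drift_amplitude = 0)
  cs <- coh$cases[[1]]
  b <- coh$protocol$b_values
  i <- which(cs$masks$dwi$prostate)[1]
  sig <- cs$dwi[cbind(arrayInd(i, dim(cs$truth$ADCk))[rep(1, length(b)), ],
                      seq_along(b))]
  expect_equal(sig, kurtosis_signal(b, cs$truth$S0_dwi[i], cs$truth$ADCk[i],
                                    cs$truth$K[i]), tolerance = 1e-10)
})
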