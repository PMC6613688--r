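test_that("feature AUC handles perfect separation, inversion and ties", {
  expect_equal(feature_auc(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1.0)
  expect_equal(feature_auc(c(4, 3, 2, 1), c(-1, -1, 1, 1)), 1.0) # flip rule
  expect_equal(feature_auc_raw(c(4, 3, 2, 1), c(-1, -1, 1, 1)), 0.0)
  expect_error(feature_auc(1:4, rep(1, 4)), "both classes")
  set.seed(81)
  for (i in 1:5) {
    v <- sample(1:5, 8, replace = TRUE) # ties likely
    y <- c(rep(-1, 3), rep(1, 5))
    raw <- oracle_auc(v, y)
    expect_equal(feature_auc_raw(v, y), raw)
    expect_equal(feature_auc(v, y), max(raw, 1 - raw))
  }
})

test_that("the AUC filter breaks boundary ties by ascending column index", {
  y <- c(rep(-1, 4), rep(1, 4))
  base <- c(1, 2, 3, 4, 5, 6, 7, 8) # perfectly separating
  weak <- c(1, 8, 2, 7, 3, 6, 4, 5) # interleaved: AUC < 1
  x <- cbind(a = weak, b = base, c = base, d = base) # b, c, d tie at AUC 1
  got <- select_top_fraction(x, y, 0.5) # keeps floor(0.5*4) = 2
  expect_identical(got, c(2L, 3L))
})

test_that("inner CV selection is deterministic and resolves ties to the weakest penalty", {
  set.seed(82)
  n <- 60
  y <- c(rep(-1, 20), rep(1, 40))
  x <- cbind(sep = y * 3 + rnorm(n, sd = 0.01), noise = rnorm(n))
  cfg <- cv_config(penalty = "l2", seed = 5)
  a1 <- inner_select_hyperparam(x, y, cfg)
  a2 <- inner_select_hyperparam(x, y, cfg)
  expect_identical(a1, a2)
  expect_equal(a1, 10) # all omegas reach AUC 1; tie goes to the largest
})

test_that("inner CV AUC stays in the no-signal band on pure noise", {
  set.seed(83)
  aucs <- replicate(30, {
    y <- sample(c(rep(-1, 20), rep(1, 40)))
    x <- matrix(rnorm(60 * 5), 60, 5)
    fold <- mpradiomics:::.stratified_folds(y, 10, sample.int(1e6, 1))
    res <- c()
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- mpradiomics:::.glmnet_fit(x[tr, ], y[tr], "l2", 1)
      res <- c(res, feature_auc_raw(
        mpradiomics:::.glmnet_link(fit, x[!tr, , drop = FALSE]), y[!tr]))
    }
    mean(res)
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("LPOCV reaches AUC 1 on a perfectly separating feature", {
  t <- toy_table(10, 5, seed = 84, low_fraction = 0.4)
  x <- t$features
  x[, 1] <- t$label * 2 + seq(0.01, 0.1, length.out = 10) # separable
  tt <- feature_table(t$patient_id, t$label, x)
  res <- run_lpocv(tt, cv_config(penalty = "l1", grid = 1, fraction = "all",
                                 seed = 3))
  expect_equal(res$auc, 1.0)
  expect_equal(res$ci[2], 1.0)
  # win scores bounded and every pair contributes exactly one win
  expect_true(all(res$scores >= 0 & res$scores <= 9))
  expect_equal(sum(res$scores), choose(10, 2))
})

test_that("LPOCV is deterministic under a fixed seed", {
  t <- toy_table(12, 8, seed = 85, low_fraction = 0.4)
  cfg <- cv_config(penalty = "l2", fraction = 0.5, seed = 11)
  r1 <- run_lpocv(t, cfg)
  r2 <- run_lpocv(t, cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$alphas, r2$alphas)
  expect_identical(r1$selected, r2$selected)
})

test_that("held-out rows never influence a round's feature selection", {
  t <- toy_table(12, 10, seed = 86, low_fraction = 0.4, effect = 1)
  cfg <- cv_config(penalty = "l2", grid = 1, fraction = 0.3, seed = 2)
  r1 <- run_lpocv(t, cfg)
  # corrupt the two rows held out in round 1 (the pair (1, 2))
  x2 <- t$features
  x2[1, ] <- 1e6 * seq_len(ncol(x2))
  x2[2, ] <- -1e6
  t2 <- feature_table(t$patient_id, t$label, x2)
  r2 <- run_lpocv(t2, cfg)
  expect_identical(r1$selected[[1]], r2$selected[[1]])
  expect_identical(r1$alphas[1], r2$alphas[1])
})

test_that("win-score ROC is equivalent to scoring with a fixed ranker", {
  set.seed(87)
  scores <- rnorm(15)
  y <- c(rep(-1, 5), rep(1, 10))
  wins <- numeric(15)
  for (i in 1:14) for (j in (i + 1):15) {
    h <- (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    wins[i] <- wins[i] + h
    wins[j] <- wins[j] + 1 - h
  }
  expect_equal(feature_auc_raw(wins, y), feature_auc_raw(scores, y))
})

test_that("the DeLong-type CI behaves like a rank statistic's CI", {
  set.seed(88)
  y <- c(rep(-1, 15), rep(1, 35))
  s <- rnorm(50) + (y > 0) * 1.2
  ci <- auc_with_ci(s, y)
  expect_true(ci[2] <= ci[1] && ci[1] <= ci[3])
  # invariance under strictly monotone transforms
  expect_equal(auc_with_ci(exp(s), y), ci)
  # perfectly separated scores: degenerate CI at 1
  expect_equal(unname(auc_with_ci(y * 2 + 1, y)), c(1, 1, 1))
  # width shrinks with n at fixed true AUC
  widths <- vapply(c(40, 100, 400), function(n) {
    yy <- c(rep(-1, n * 0.3), rep(1, n * 0.7))
    mean(replicate(30, {
      ss <- rnorm(n) + (yy > 0) * 1.0
      ci <- auc_with_ci(ss, yy)
      ci[3] - ci[2]
    }))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the final model trains on the filtered features deterministically", {
  t <- toy_table(20, 50, seed = 89, effect = 3, low_fraction = 0.25)
  cfg <- cv_config(penalty = "l1", fraction = 0.1, seed = 4)
  m1 <- train_final_model(t, cfg)
  m2 <- train_final_model(t, cfg)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_length(m1$selected_features, floor(0.1 * 50))
  expect_equal(m1$training_auc, 1.0) # effect 3 separates in-sample
})
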