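test_that("correlation filter matches the closed-form Pearson p", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  r <- oracle_pearson(x, y)
  expect_equal(fcmvpa:::pearson_p(r, 5), oracle_pearson_p(r, 5))
  expect_equal(fcmvpa:::pearson_p(r, 5), 2 * pt(-abs(r * sqrt(3 / (1 - r^2))), 3))

  set.seed(51)
  feats <- cbind(sig = y, matrix(rnorm(5 * 4), 5, 4))
  sel <- correlation_feature_filter(cbind(y, feats), y, alpha = 0.05)
  expect_true(1 %in% sel)        # the label itself is always kept
  expect_error(correlation_feature_filter(feats, rep(2, 5)),
               "zero-variance")
  expect_error(correlation_feature_filter(feats[1:3, ], y[1:3]),
               "4 subjects")
})

test_that("on null features the filter keeps about alpha of them", {
  set.seed(52)
  kept <- vapply(1:40, function(i) {
    feats <- matrix(rnorm(20 * 50), 20, 50)
    length(correlation_feature_filter(feats, rnorm(20), alpha = 0.05))
  }, numeric(1))
  # binomial(50, 0.05) mean 2.5 per replicate
  expect_gt(mean(kept) / 50, 0.02)
  expect_lt(mean(kept) / 50, 0.09)
})

test_that("evaluate_prediction computes r and RMSE on the native scale", {
  act <- c(10, 12, 14, 11)
  expect_equal(evaluate_prediction(act, act), list(r = 1, rmse = 0))
  ev <- evaluate_prediction(act + 2, act)
  expect_equal(ev$r, 1)
  expect_equal(ev$rmse, 2)
  pred <- c(1, 2, 3, 4)
  act2 <- c(2, 2, 4, 3)
  ev2 <- evaluate_prediction(pred, act2)
  expect_equal(ev2$r, oracle_pearson(pred, act2))
  expect_equal(ev2$rmse, sqrt(mean((pred - act2)^2)))
  expect_equal(evaluate_prediction(rep(1, 4), act2)$r, 0)  # ties convention
  expect_error(evaluate_prediction(1:3, 1:4), "length mismatch")
  expect_error(evaluate_prediction(1:4, rep(1, 4)), "constant actual")
})

test_that("LOOCV SVR recovers a strong linear signal", {
  set.seed(53)
  x <- matrix(rnorm(30 * 20), 30, 20)
  y <- 2 * x[, 1] - 1.5 * x[, 2] + x[, 3]
  run <- loocv_regress(x, y)
  expect_gt(run$r, 0.95)
  expect_length(run$predicted, 30)
})

test_that("changing a held-out label does not change its prediction
          (no leakage)", {
  set.seed(54)
  x <- matrix(rnorm(12 * 15), 12, 15)
  y <- rnorm(12)
  y2 <- y
  y2[4] <- y[4] + 50
  r1 <- loocv_regress(x, y)
  r2 <- loocv_regress(x, y2)
  expect_equal(r1$predicted[4], r2$predicted[4])
})

test_that("folds with an empty selection predict the training mean", {
  set.seed(55)
  x <- matrix(rnorm(10 * 8), 10, 8)
  y <- rnorm(10)
  run <- loocv_regress(x, y, alpha = 1e-9)
  expect_true(all(lengths(run$selected) == 0))
  expect_equal(run$predicted, vapply(1:10, function(i) mean(y[-i]),
                                     numeric(1)))
})

test_that("filtering before cross-validation leaks: permuted labels still
          'predict' under the broken variant", {
  set.seed(56)
  honest <- leaky <- numeric(15)
  for (i in 1:15) {
    x <- matrix(rnorm(20 * 200), 20, 200)
    y <- rnorm(20)
    honest[i] <- loocv_regress(x, y, filter_scope = "fold")$r
    leaky[i] <- loocv_regress(x, y, filter_scope = "all")$r
  }
  expect_lt(abs(mean(honest)), 0.25)           # centred near zero
  expect_gt(mean(leaky), mean(honest) + 0.3)   # optimistic bias
  expect_gt(mean(leaky), 0.3)
})

test_that("fold-wise selection frequency is enriched at ground-truth
          score-linked edges", {
  cfg <- synthetic_config(n_rois = 10, n_patient = c(25, 25),
                          n_control = c(1, 1), t_volumes = c(150, 150),
                          n_disc_edges = 0, n_score_edges = 5,
                          score_noise_sd = 0.3, measurement_noise_sd = 0.1,
                          seed = 57)
  coh <- generate_cohort(cfg)
  ph <- coh$phenotype
  pat <- ph$group == "patient"
  f <- fc_feature_table(coh$series[ph$subject_id[pat]])
  run <- loocv_regress(f, ph$joa_pre[pat])
  freq <- tabulate(unlist(run$selected), nbins = ncol(f))
  top5 <- order(-freq, seq_along(freq))[1:5]
  hits <- sum(top5 %in% coh$truth$score_edges)
  expect_gte(hits, 3)
  # hypergeometric tail: >= `hits` of 5 draws from 45 with 5 special
  expect_lt(phyper(hits - 1, 5, 40, 5, lower.tail = FALSE), 0.01)
})

test_that("permutation test for SVR counts both tails correctly", {
  set.seed(58)
  x <- matrix(rnorm(14 * 10), 14, 10)
  y <- 2 * x[, 1] + rnorm(14, 0, 0.3)
  pt <- permutation_test_regression(x, y, n_perm = 19)
  expect_lt(unname(pt$r$p), 0.2)
  expect_lt(unname(pt$rmse$p), 0.2)
  expect_equal(pt$observed$r, loocv_regress(x, y)$r)
})

test_that("cross-site SVR transfers a shared signal and respects the
          translation property", {
  set.seed(59)
  x1 <- matrix(rnorm(25 * 15), 25, 15)
  x2 <- matrix(rnorm(25 * 15), 25, 15)
  y1 <- 2 * x1[, 1] - x1[, 2] + rnorm(25, 0, 0.2)
  y2 <- 2 * x2[, 1] - x2[, 2] + rnorm(25, 0, 0.2)
  xs <- cross_site_regress(x1, y1, x2, y2)
  expect_gt(xs[["1->2"]]$r, 0.7)
  expect_gt(xs[["2->1"]]$r, 0.7)

  shift <- 10
  xs_shift <- cross_site_regress(x1, y1, x2, y2 + shift)
  expect_equal(xs_shift[["1->2"]]$predicted, xs[["1->2"]]$predicted)
  expect_equal(xs_shift[["1->2"]]$r, xs[["1->2"]]$r)
  expect_equal(xs_shift[["1->2"]]$rmse, shift,
               tolerance = 0.2)

  # independent feature-label linkage does not transfer
  y2_null <- sample(y2)
  xs_null <- cross_site_regress(x1, y1, x2, y2_null)
  expect_lt(abs(xs_null[["1->2"]]$r), 0.5)
  expect_error(cross_site_regress(x1, y1, x2[, 1:3], y2),
               "dimensionality")
})

test_that("minmax label scaling puts RMSE on the unit scale", {
  set.seed(60)
  x <- matrix(rnorm(20 * 10), 20, 10)
  y <- 10 + 3 * x[, 1] + rnorm(20, 0, 0.5)
  native <- loocv_regress(x, y, label_scaling = "native")
  scaled <- loocv_regress(x, y, label_scaling = "minmax")
  expect_lt(scaled$rmse, native$rmse)
  # held-out actuals are mapped with the training fold's scaler, so the
  # fold extremes can land slightly outside [0, 1]
  expect_true(all(scaled$actual >= -0.5 & scaled$actual <= 1.5))
  expect_equal(scaled$r, native$r, tolerance = 0.15)
  expect_error(loocv_regress(x, rep(3, 20)), "constant labels")
  expect_error(loocv_regress(x[1:4, ], y[1:4]), "at least 5")
})
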