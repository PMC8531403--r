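test_that("select_top_features sizes the set by round-half-up and breaks
          ties by index", {
  w <- rnorm(6670)
  expect_length(select_top_features(w, 0.05), 334)
  expect_length(select_top_features(w, 0.15), 1001)
  expect_length(select_top_features(w, 0.25), 1668)
  expect_length(select_top_features(w, 0.30), 2001)
  expect_length(select_top_features(w, 1), 6670)
  expect_equal(select_top_features(c(1, 1, 1, 1), 0.5), c(1L, 2L))
  expect_equal(select_top_features(c(0.1, -5, 2, 0.3), 0.5), c(2L, 3L))
  expect_error(select_top_features(rnorm(100), 0.001), "zero features")
  expect_error(select_top_features(c(1, NA), 0.5), "finite")
})

test_that("LOOCV classifies separable classes perfectly at every fraction", {
  set.seed(41)
  d <- make_gaussian_classes(6, 30, delta = 4)
  cv <- loocv_classify(d$x, d$y, grid = c(0.1, 0.5, 1))
  expect_equal(unname(cv$accuracy), c(1, 1, 1))
  expect_equal(cv$n_folds, 12)
  expect_true(all(cv$decision_values[d$y == "patient", ] > 0))
  expect_true(all(cv$decision_values[d$y == "control", ] < 0))
})

test_that("fraction 1.0 reproduces the no-selection analysis exactly", {
  set.seed(42)
  d <- make_gaussian_classes(7, 25, delta = 0.8)
  cv_both <- loocv_classify(d$x, d$y, grid = c(0.2, 1))
  cv_one <- loocv_classify(d$x, d$y, grid = 1)
  expect_identical(cv_both$predictions[, "1"], cv_one$predictions[, "1"])
  expect_identical(cv_both$decision_values[, "1"],
                   cv_one$decision_values[, "1"])
  expect_equal(cv_both$selected[["1"]][[1]], seq_len(25))
})

test_that("duplicating every feature leaves fraction-1.0 predictions
          unchanged", {
  set.seed(43)
  d <- make_gaussian_classes(6, 10, delta = 1.5)
  cv1 <- loocv_classify(d$x, d$y, grid = 1)
  cv2 <- loocv_classify(cbind(d$x, d$x), d$y, grid = 1)
  expect_equal(cv1$predictions[, "1"], cv2$predictions[, "1"])
})

test_that("LOOCV accuracy is invariant to subject ordering", {
  set.seed(44)
  d <- make_gaussian_classes(6, 15, delta = 0.7)
  perm <- sample(length(d$y))
  cv1 <- loocv_classify(d$x, d$y, grid = c(0.2, 0.6, 1))
  cv2 <- loocv_classify(d$x[perm, ], d$y[perm], grid = c(0.2, 0.6, 1))
  expect_equal(cv1$accuracy, cv2$accuracy)
})

test_that("with a strong signal, some selection fraction does at least as
          well as no selection", {
  set.seed(45)
  cfg <- synthetic_config(n_rois = 10, n_patient = c(10, 10),
                          n_control = c(10, 10), t_volumes = c(100, 100),
                          n_disc_edges = 5, disc_effect = 0.5,
                          n_score_edges = 0, seed = 45)
  coh <- generate_cohort(cfg)
  f <- fc_feature_table(coh$series)
  g <- factor(coh$phenotype$group, levels = c("control", "patient"))
  cv <- loocv_classify(f, g, grid = c(0.1, 0.25, 0.5, 1))
  expect_gte(max(cv$accuracy), cv$accuracy[["1"]])
})

test_that("classification inputs are validated", {
  x <- matrix(rnorm(20), 4, 5)
  expect_error(loocv_classify(x, factor(c("a", "a", "a", "b"))),
               "2 subjects per class")
  expect_error(loocv_classify(x, factor(rep("a", 4))), "two classes")
  expect_error(loocv_classify(x, factor(c("a", "a", "b", "b")),
                              grid = c(0.5, 0.2)),
               "strictly increasing")
})

test_that("permutation p counts the null tail and floors at 1/n_perm", {
  pn <- fcmvpa:::perm_null(observed = c(f1 = 0.2),
                           null = matrix(c(0.5, 0.6, 0.7, 0.8)),
                           n_perm = 4, tail = "ge")
  expect_equal(unname(pn$p), 1)
  expect_false(pn$floor)
  pn2 <- fcmvpa:::perm_null(observed = c(f1 = 0.95),
                            null = matrix(c(0.5, 0.6, 0.7, 0.8)),
                            n_perm = 4, tail = "ge")
  expect_equal(unname(pn2$p), 0)
  expect_true(pn2$floor)
  expect_match(pn2$p_label, "^< 0.25")
  # le tail (used for RMSE): smaller is better
  pn3 <- fcmvpa:::perm_null(observed = c(s = 2), null = matrix(c(1, 1.5)),
                            n_perm = 2, tail = "le")
  expect_equal(unname(pn3$p), 1)
})

test_that("a separable cohort yields a floored permutation p", {
  set.seed(46)
  d <- make_gaussian_classes(5, 10, delta = 5)
  pt <- permutation_test_accuracy(d$x, d$y, grid = 1, n_perm = 19)
  expect_equal(unname(pt$observed), 1)
  expect_true(pt$p[1] < 0.2)
  pt_fixed <- permutation_test_accuracy(d$x, d$y, grid = 1, n_perm = 9,
                                        perm_fixed_features = TRUE)
  expect_equal(unname(pt_fixed$observed), 1)
})

test_that("bonferroni adjustment uses a strict alpha/m threshold", {
  b <- bonferroni_adjust(rep(0.01, 20), alpha = 0.05)
  expect_equal(b$threshold, 0.0025)
  expect_false(any(b$flags))
  expect_equal(bonferroni_adjust(0.04, alpha = 0.05)$threshold, 0.05)
  expect_true(bonferroni_adjust(0.04, alpha = 0.05)$flags)
  # exactly at the threshold is not significant (strict inequality)
  expect_false(bonferroni_adjust(rep(0.0025, 20), alpha = 0.05)$flags[1])
  expect_true(bonferroni_adjust(c(0.002, rep(0.5, 19)),
                                alpha = 0.05)$flags[1])
})

test_that("roc_auc matches the pair-counting oracle and pROC", {
  # hand example: 6 scores, counted by hand as 8/9
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labs <- factor(c("p", "p", "n", "p", "n", "n"), levels = c("n", "p"))
  r <- roc_auc(scores, labs, positive = "p")
  expect_equal(r$auc, 8 / 9)
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$specificity[1], 1)
  expect_equal(r$sensitivity[length(r$thresholds)], 1)

  expect_equal(roc_auc(1:6, labs, positive = "p")$auc,
               oracle_auc(1:6, labs == "p"))
  expect_equal(roc_auc(rep(1, 6), labs)$auc, 0.5)
  expect_equal(roc_auc(c(3, 3, 1, 3, 1, 1), labs, positive = "p")$auc, 1)

  set.seed(47)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.25), n, TRUE)   # heavy ties
    labs <- factor(ifelse(pos, "p", "n"), levels = c("n", "p"))
    got <- roc_auc(scores, labs, positive = "p")$auc
    expect_equal(got, oracle_auc(scores, pos))
    expect_equal(got,
                 as.numeric(suppressMessages(pROC::auc(
                   pROC::roc(pos, scores, direction = "<", quiet = TRUE)))))
  }
  expect_error(roc_auc(1:3, factor(rep("p", 3))), "both classes")
})

test_that("cross-site classification is direction-sensitive and validates
          dimensions", {
  set.seed(48)
  d1 <- make_gaussian_classes(8, 12, delta = 3)
  cs <- cross_site_classify(d1$x, d1$y, d1$x, d1$y, grid = c(0.5, 1))
  expect_equal(unname(cs$mean_accuracy), c(1, 1))
  expect_equal(cs$directions[["1->2"]]$roc[["1"]]$auc, 1)

  # a test site whose class-conditional means are exchanged is classified
  # below chance: the metric is direction-sensitive
  d2 <- make_gaussian_classes(8, 12, delta = 3)
  y2 <- factor(ifelse(d2$y == "patient", "control", "patient"),
               levels = c("control", "patient"))
  cs2 <- cross_site_classify(d1$x, d1$y, d2$x, y2, grid = 1)
  expect_lt(cs2$directions[["1->2"]]$accuracy[["1"]], 0.5)

  expect_error(cross_site_classify(d1$x, d1$y, d1$x[, 1:5], d1$y),
               "different edge counts")
})
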