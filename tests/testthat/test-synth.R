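test_that("JOA recovery and recovery rate match their definitions", {
  expect_equal(joa_recovery(11.8, 15.7), 3.9)
  expect_equal(joa_recovery(12, 12), 0)
  expect_equal(joa_recovery(14, 10), -4)
  expect_equal(joa_recovery_rate(11, 14), 0.5)
  expect_equal(joa_recovery_rate(16, 17), 1.0)
  expect_error(joa_recovery_rate(17, 17), "zero denominator")
  expect_error(joa_recovery(-1, 5), "outside")
  expect_error(joa_recovery(5, 18), "outside")
  expect_error(joa_recovery_rate(18, 12), "outside")
})

test_that("synthetic correlation matrices are symmetric, unit-diagonal,
          PSD, and carry the imposed Fisher-z shift", {
  set.seed(101)
  for (rep in 1:10) {
    r <- sample(8:20, 1)
    base <- fcmvpa:::nearest_pd_corr(fcmvpa:::base_correlation(r, avg = 0.2))
    expect_equal(base, t(base))
    expect_equal(unname(diag(base)), rep(1, r))
    expect_gte(min(eigen(base, symmetric = TRUE)$values), -1e-8)

    edges <- sample.int(n_edges(r), 5)
    delta <- runif(1, 0.3, 0.7)
    shifted <- fcmvpa:::shift_edges_z(base, edges, delta)
    expect_equal(shifted, t(shifted))
    expect_equal(unname(diag(shifted)), rep(1, r))
    expect_gte(min(eigen(shifted, symmetric = TRUE)$values), -1e-8)
    got <- fisher_z(shifted[lower.tri(shifted)])[edges]
    want <- fisher_z(base[lower.tri(base)])[edges] + delta
    expect_lt(max(abs(got - want)), 0.02 * delta + 0.01)
  }
})

test_that("equal seeds give bitwise-identical cohorts, different seeds differ", {
  cfg <- synthetic_config(n_rois = 8, n_patient = c(3, 3),
                          n_control = c(3, 3), t_volumes = c(40, 60),
                          n_disc_edges = 3, n_score_edges = 3, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  cfg$seed <- 12L
  c3 <- generate_cohort(cfg)
  expect_false(identical(c1$series, c3$series))
})

test_that("null configuration is exchangeable: edge-wise p-values are
          approximately uniform and scores are noise", {
  cfg <- synthetic_config(n_rois = 10, n_patient = c(15, 15),
                          n_control = c(15, 15), t_volumes = c(80, 80),
                          n_disc_edges = 0, disc_effect = 0,
                          n_score_edges = 0, seed = 21)
  coh <- generate_cohort(cfg)
  f <- fc_feature_table(coh$series)
  g <- factor(coh$phenotype$group, levels = c("control", "patient"))
  es <- edgewise_group_test(f, g)
  expect_gt(stats::ks.test(es$p, "punif")$p.value, 0.001)
  expect_equal(sum(es$fdr_pass), 0)
})

test_that("the imposed group z-shift is recovered empirically
          (Monte-Carlo over replicate cohorts)", {
  # noise channels off to isolate the disc_effect mechanism
  diffs <- vapply(1:50, function(rep) {
    cfg <- synthetic_config(n_rois = 10, n_patient = c(20, 20),
                            n_control = c(20, 20), t_volumes = c(200, 200),
                            n_disc_edges = 5, disc_effect = 0.6,
                            n_score_edges = 0, subject_z_sd = 0,
                            measurement_noise_sd = 0, seed = 300 + rep)
    coh <- generate_cohort(cfg)
    f <- fc_feature_table(coh$series)
    pat <- coh$phenotype$group == "patient"
    mean(colMeans(f[pat, coh$truth$disc_edges, drop = FALSE]) -
           colMeans(f[!pat, coh$truth$disc_edges, drop = FALSE]))
  }, numeric(1))
  expect_equal(mean(diffs), 0.6, tolerance = 0.05)
})

test_that("synthetic configs validate their fields", {
  expect_error(synthetic_config(n_patient = c(0, 5)))
  expect_error(synthetic_config(n_rois = 4, n_disc_edges = 5,
                                n_score_edges = 5),
               "more ground-truth edges")
  expect_error(synthetic_config(base_corr_mean = 1.2))
  cfg <- synthetic_config(n_rois = 6, n_patient = c(2, 2),
                          n_control = c(2, 2), t_volumes = c(30, 30),
                          n_disc_edges = 0, n_score_edges = 0, seed = 5)
  coh <- generate_cohort(cfg)
  ph <- coh$phenotype
  expect_true(all(is.na(ph$joa_pre[ph$group == "control"])))
  pre <- ph$joa_pre[ph$group == "patient"]
  post <- ph$joa_post[ph$group == "patient"]
  expect_true(all(pre >= 0 & pre <= 17 & post >= 0 & post <= 17))
  expect_true(all(vapply(coh$series, function(s) !anyNA(s), logical(1))))
})

test_that("cohorts written to disk round-trip through plain text", {
  cfg <- synthetic_config(n_rois = 6, n_patient = c(2, 2),
                          n_control = c(2, 2), t_volumes = c(20, 20),
                          n_disc_edges = 2, n_score_edges = 2, seed = 8)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$phenotype, coh$phenotype)
  expect_equal(back$truth$disc_edges, coh$truth$disc_edges)
  expect_equal(unname(back$series[[1]]),
               unname(round(coh$series[[1]], 6)), tolerance = 1e-12)
})
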