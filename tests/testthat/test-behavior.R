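# Learning measures, subgroup clustering, and the PC1 learning score.

test_that("bin medians are robust and match hand cases", {
  tt <- data.frame(bin = rep(1:2, each = 8),
                   error_deg = c(rep(45, 8),
                                 c(10, 10, 10, 10, 10, 10, 10, 100)))
  m <- binned_median_error(tt, n_bins = 2)
  expect_equal(m, c(45, 10))
  expect_error(binned_median_error(tt, n_bins = 3), "empty bin 3")
  # bins with fewer than 8 trials (discarded timeouts) are still scored
  tt2 <- data.frame(bin = c(1, 1, 1), error_deg = c(4, 6, 100))
  expect_equal(binned_median_error(tt2, n_bins = 1), 6)
})

test_that("learning measures: savings identity, constants, window widths", {
  b1 <- rep(10, 40); b2 <- rep(10, 40)
  m <- learning_measures(b1, b2)
  expect_equal(unname(m), c(10, 10, 10, 10, 0))
  b1[1:3] <- 30; b2[1:3] <- 10
  m2 <- learning_measures(b1, b2)
  expect_equal(unname(m2["savings"]), 20)
  expect_identical(m2[["savings"]], m2[["early1"]] - m2[["early2"]])
  # early window covers bins 1-3 = 24 trials at 8 trials per bin
  expect_equal(3 * 8, 24)
  expect_error(learning_measures(b1[1:39], b2), "40")
})

test_that("noiseless generated trials reproduce the closed-form decay curve", {
  cfg <- cohort_config(n_subjects = 2, n_regions = 10, n_volumes = 64,
                       subgroup_sizes = c(FF = 1, SS = 1, SF = 0),
                       behav_noise_sd = 0, coupling_jitter = 0, seed = 5)
  tr <- generate_behavioral_trials(cfg, 1)
  tau <- attr(tr, "tau")
  d1 <- tr[tr$day == 1, ]
  meds <- binned_median_error(d1)
  t_idx <- seq_len(320)
  curve <- 40 * exp(-t_idx / tau[1]) + 5
  expected <- sapply(1:40, function(b) median(curve[(b - 1) * 8 + 1:8]))
  expect_equal(meds, expected, tolerance = 1e-12)
  # instant-learning limit: tiny tau on both days
  cfg0 <- cohort_config(n_subjects = 1, n_regions = 10, n_volumes = 64,
                        subgroup_sizes = c(FF = 1, SS = 0, SF = 0),
                        behav_noise_sd = 0, coupling_jitter = 0,
                        effect_slope = 0,
                        tau_by_profile = list(FF = c(1e-9, 1e-9),
                                              SS = c(1, 1), SF = c(1, 1)),
                        seed = 5)
  m0 <- trial_learning_measures(generate_behavioral_trials(cfg0, 1))
  expect_equal(unname(m0), c(5, 5, 5, 5, 0))
  # SF: slow day 1, fast day 2 -> positive savings
  cfg_sf <- cohort_config(n_subjects = 1, n_regions = 10, n_volumes = 64,
                          subgroup_sizes = c(FF = 0, SS = 0, SF = 1),
                          behav_noise_sd = 0, seed = 6)
  m_sf <- trial_learning_measures(generate_behavioral_trials(cfg_sf, 1))
  expect_gt(m_sf[["early1"]], m_sf[["early2"]])
  expect_gt(m_sf[["savings"]], 0)
})

test_that("k-means selects planted k = 3 and recovers profiles", {
  set.seed(7)
  ok <- 0
  for (r in 1:10) {
    # three spherical Gaussian clusters separated by ~10 noise sd
    centers <- rbind(c(0, 0, 0, 0, 0), c(10, 10, 0, 0, 0),
                     c(0, 0, 10, 10, 10))
    truth <- rep(1:3, times = c(15, 10, 7))
    x <- centers[truth, ] + matrix(rnorm(32 * 5, sd = 1), 32)
    cl <- cluster_participants(x, k_range = 2:6, restarts = 50, seed = r)
    if (cl$agreement && cl$k_selected == 3 &&
        ari(cl$labels, truth) > 0.99) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("two shifted copies of a cloud select k = 2", {
  set.seed(9)
  cloud <- matrix(rnorm(60), 12, 5)
  x <- rbind(cloud, cloud + 30)
  cl <- cluster_participants(x, k_range = 2:5, restarts = 50, seed = 11)
  expect_equal(c(k = cl$k_selected), c(k = 2))
  expect_true(cl$agreement)
})

test_that("clustering is equivariant under subject reordering", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40), 8, 5), matrix(rnorm(40, 12), 8, 5))
  cl <- cluster_participants(x, k_range = 2:4, restarts = 50, seed = 15)
  perm <- sample(16)
  cl_p <- cluster_participants(x[perm, ], k_range = 2:4, restarts = 50,
                               seed = 15)
  expect_equal(cl_p$k_selected, cl$k_selected)
  expect_equal(ari(cl_p$labels, cl$labels[perm]), 1)
})

test_that("Calinski-Harabasz agrees with the vegan cascadeKM oracle", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40), 8, 5), matrix(rnorm(40, 6), 8, 5))
  km <- kmeans(x, 2, nstart = 20)
  ours <- dynmod:::.calinski_harabasz(x, km$cluster)
  cc <- vegan::cascadeKM(x, 2, 2, iter = 50, criterion = "calinski")
  expect_equal(ours, unname(cc$results["calinski", 1]), tolerance = 1e-6)
})

test_that("clustering significance: floor on planted clusters, calibration on nulls", {
  set.seed(19)
  # strongly planted: no null iteration should beat the observed indices
  truth <- rep(1:3, times = c(8, 7, 5))
  centers <- matrix(rnorm(15, sd = 12), 3, 5)
  x <- centers[truth, ] + matrix(rnorm(100), 20, 5)
  sig <- clustering_significance(x, k_range = 2:4, restarts = 20,
                                 n_iter = 100, seed = 21)
  expect_lte(sig$p[["silhouette"]], 0.02)
  expect_true(all(sig$p >= 0 & sig$p <= 1))
  expect_error(clustering_significance(x, n_iter = 50), "at least 100")

  # self-null calibration: data drawn from the multivariate normal itself;
  # rejection rate at alpha = 0.05 within the binomial 95% CI
  nrep <- 40
  rej <- 0
  for (r in seq_len(nrep)) {
    xb <- MASS::mvrnorm(16, rep(0, 3), diag(3))
    sb <- clustering_significance(xb, k_range = 2:3, restarts = 10,
                                  n_iter = 100, seed = 100 + r)
    if (sb$p[["silhouette"]] < 0.05) rej <- rej + 1
  }
  ci <- 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(abs(rej / nrep - 0.05), ci + 1e-9)
})

test_that("PC1: rank-1 data, sign convention, and FF/SS separation", {
  # five perfectly correlated variables: PC1 explains everything
  set.seed(23)
  v <- rnorm(12)
  x <- cbind(v, 2 * v, v, 3 * v, -v)
  colnames(x) <- c("early1", "late1", "early2", "late2", "savings")
  emb <- behavioral_pc1(x)
  expect_equal(emb$explained[1], 1, tolerance = 1e-12)
  # sign convention: higher PC1 = lower mean early error
  expect_lt(cor(emb$pc1, rowMeans(x[, c("early1", "early2")])), 0)
  # flipping the sign of all inputs leaves |loadings| unchanged
  emb2 <- behavioral_pc1(-x)
  expect_equal(abs(emb2$loadings), abs(emb$loadings), tolerance = 1e-10)
  expect_error(behavioral_pc1(cbind(x[, 1:4], 0)), "zero-variance")
})

test_that("synthetic cohorts: PC1 separates FF from SS almost perfectly", {
  n_rep <- 20
  ok <- 0
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_regions = 10, n_volumes = 64, seed = r)
    meas <- t(sapply(seq_len(32), function(s)
      trial_learning_measures(generate_behavioral_trials(cfg, s))))
    emb <- behavioral_pc1(meas)
    prof <- subject_profiles(cfg)
    ff <- emb$pc1[prof == "FF"]; ss <- emb$pc1[prof == "SS"]
    # best 1-D threshold classification accuracy between FF and SS
    thr_grid <- sort(c(ff, ss))
    acc <- max(sapply(thr_grid, function(th)
      (sum(ff > th) + sum(ss <= th)) / (length(ff) + length(ss))))
    if (acc >= 0.95) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("full behavioral pipeline recovers planted subgroups from trials", {
  n_rep <- 10
  ok <- 0
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_regions = 10, n_volumes = 64, seed = 500 + r)
    meas <- t(sapply(seq_len(32), function(s)
      trial_learning_measures(generate_behavioral_trials(cfg, s))))
    truth <- as.integer(factor(subject_profiles(cfg)))
    cl <- cluster_participants(meas, k_range = 2:6, restarts = 100,
                               seed = r)
    if (cl$k_selected == 3 && ari(cl$labels, truth) > 0.9) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
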