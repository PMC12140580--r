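# Synthetic cohort generator: configuration contracts, planted correlation
# structure, determinism, serialization round-trips.

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 10,
                             subgroup_sizes = c(FF = 5, SS = 3, SF = 1)),
               "sum to n_subjects")
  expect_error(cohort_config(coupling_strength_by_profile =
                               c(FF = 1.2, SS = 0.3, SF = 0.5)),
               "in \\(0, 1\\)")
  expect_error(cohort_config(cohesion_rate_by_profile =
                               c(FF = -1, SS = 0, SF = 0)), "nonnegative")
  expect_error(cohort_config(tau_by_profile = list(FF = c(-1, 1),
                                                   SS = c(1, 1),
                                                   SF = c(1, 1))),
               "nonpositive tau")
  expect_error(cohort_config(n_volumes = 16), "series too short")
})

test_that("noiseless panels have within-module correlation 1, between ~ 0", {
  cfg <- cohort_config(n_subjects = 1, n_regions = 12, n_volumes = 160,
                       n_modules_planted = 2,
                       subgroup_sizes = c(FF = 1, SS = 0, SF = 0),
                       cohesion_rate_by_profile = c(FF = 0, SS = 0, SF = 0),
                       disjoint_rate_by_profile = c(FF = 0, SS = 0, SF = 0),
                       noise_sd = 0, seed = 3)
  g <- generate_modular_timeseries(cfg, 1)
  cc <- cor(t(g$panel$x))
  modules <- g$truth$block_partitions[1, ]
  within <- cc[outer(modules, modules, "==") & upper.tri(cc)]
  between <- cc[outer(modules, modules, "!=") & upper.tri(cc)]
  expect_equal(within, rep(1, length(within)), tolerance = 1e-10)
  expect_lt(max(abs(between)), 0.35) # independent latents, finite series
  # no switch events: partitions constant across blocks
  expect_true(all(apply(g$truth$block_partitions, 2,
                        function(cl) length(unique(cl)) == 1)))
})

test_that("planted within-module correlation is recovered within 0.05", {
  for (rho in c(0.3, 0.55, 0.8)) {
    cfg <- cohort_config(n_subjects = 1, n_regions = 20, n_volumes = 192,
                         n_modules_planted = 2,
                         subgroup_sizes = c(FF = 1, SS = 0, SF = 0),
                         coupling_strength_by_profile =
                           c(FF = rho, SS = 0.5, SF = 0.5),
                         cohesion_rate_by_profile = c(FF = 0, SS = 0, SF = 0),
                         disjoint_rate_by_profile = c(FF = 0, SS = 0, SF = 0),
                         coupling_jitter = 0, seed = 7)
    # average the estimate over several noise streams (long-series limit)
    ests <- sapply(1:6, function(sc) {
      g <- generate_modular_timeseries(cfg, 1, scan = sc %% 2 + 1)
      cfg2 <- cfg; cfg2$seed <- cfg$seed + sc
      g <- generate_modular_timeseries(cfg2, 1)
      cc <- cor(t(g$panel$x))
      modules <- g$truth$block_partitions[1, ]
      mean(cc[outer(modules, modules, "==") & upper.tri(cc)])
    })
    expect_lt(abs(mean(ests) - rho), 0.05)
  }
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- cohort_config(n_subjects = 2, n_regions = 10, n_volumes = 64,
                       subgroup_sizes = c(FF = 1, SS = 1, SF = 0), seed = 9)
  a <- generate_modular_timeseries(cfg, 1)
  b <- generate_modular_timeseries(cfg, 1)
  expect_identical(a$panel$x, b$panel$x)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_behavioral_trials(cfg, 2),
                   generate_behavioral_trials(cfg, 2))
  # different subjects: distinct noise, same profile structure
  c1 <- generate_modular_timeseries(cfg, 2)
  expect_false(identical(a$panel$x, c1$panel$x))
})

test_that("stronger planted coupling raises measured within-module coherence", {
  # checked against the connectivity module's own estimator
  n_rep <- 10
  wins <- 0
  for (r in seq_len(n_rep)) {
    coh <- sapply(c(0.3, 0.8), function(rho) {
      cfg <- cohort_config(n_subjects = 1, n_regions = 12, n_volumes = 96,
                           n_modules_planted = 2,
                           subgroup_sizes = c(FF = 1, SS = 0, SF = 0),
                           coupling_strength_by_profile =
                             c(FF = rho, SS = 0.5, SF = 0.5),
                           coupling_jitter = 0, seed = 100 + r)
      g <- generate_modular_timeseries(cfg, 1)
      net <- build_multilayer(g$panel, threshold = 0)
      modules <- g$truth$layer_partitions
      mean(sapply(seq_along(net$layers), function(l) {
        w <- outer(modules[l, ], modules[l, ], "==") &
          upper.tri(net$layers[[l]])
        mean(net$layers[[l]][w])
      }))
    })
    if (coh[2] > coh[1]) wins <- wins + 1
  }
  expect_equal(wins, n_rep)
})

test_that("raising the cohesion rate raises recovered cohesion strength", {
  rates <- c(0, 0.5, 1, 2, 4)
  mean_coh <- sapply(rates, function(rate) {
    vals <- sapply(1:10, function(r) {
      cfg <- cohort_config(n_subjects = 1, n_regions = 30, n_volumes = 160,
                           subgroup_sizes = c(FF = 1, SS = 0, SF = 0),
                           cohesion_rate_by_profile =
                             c(FF = rate, SS = 0, SF = 0),
                           disjoint_rate_by_profile =
                             c(FF = 0.5, SS = 0, SF = 0),
                           seed = 1000 * rate + r)
      g <- generate_modular_timeseries(cfg, 1)
      mean(cohesion_strength(g$truth$layer_partitions))
    })
    mean(vals)
  })
  expect_gt(cor(rates, mean_coh, method = "spearman"), 0)
  expect_true(all(diff(mean_coh) > 0))
})

test_that("cohort serialization round-trips bit-exactly", {
  dir <- tempfile("cohort")
  cfg <- cohort_config(n_subjects = 4, n_regions = 8, n_volumes = 64,
                       subgroup_sizes = c(FF = 2, SS = 1, SF = 1), seed = 11)
  co <- generate_cohort(cfg, dir = dir)
  # manifest bookkeeping
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_subjects, 4)
  expect_length(list.files(dir, pattern = "rest[12]\\.tsv",
                           recursive = TRUE), 8)
  # overwrite protection
  expect_error(generate_cohort(cfg, dir = dir), "overwrite")
  # bit-exact panel round-trip
  back <- read_cohort(dir)
  for (s in 1:4) {
    expect_identical(back$subjects[[s]]$rest1$x, co$subjects[[s]]$rest1$x)
    expect_identical(back$subjects[[s]]$rest2$x, co$subjects[[s]]$rest2$x)
    expect_equal(back$subjects[[s]]$trials$error_deg,
                 co$subjects[[s]]$trials$error_deg, tolerance = 1e-12)
  }
  expect_identical(back$profiles, co$profiles)
  unlink(dir, recursive = TRUE)
})

test_that("planted partitions keep all modules nonempty in every window", {
  cfg <- cohort_config(n_subjects = 3, n_regions = 25, n_volumes = 160,
                       subgroup_sizes = c(FF = 1, SS = 1, SF = 1),
                       cohesion_rate_by_profile = c(FF = 4, SS = 1, SF = 2),
                       disjoint_rate_by_profile = c(FF = 1, SS = 4, SF = 2),
                       seed = 13)
  for (s in 1:3) {
    g <- generate_modular_timeseries(cfg, s)
    for (l in seq_len(nrow(g$truth$layer_partitions)))
      expect_equal(length(unique(g$truth$layer_partitions[l, ])),
                   cfg$n_modules_planted)
  }
})
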