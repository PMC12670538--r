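test_that("trial metrics are plain event arithmetic", {
  tr <- data.frame(trial = 1:2, stimulus = c("Stim1", "Stim2"),
                   choice = c("left", "right"), correct = c(TRUE, TRUE),
                   t_entry = c(10, 20), t_exit = c(11, 21),
                   t_choice = c(12.5, 22))
  m <- trial_metrics(tr)
  expect_equal(m$per_trial$reaction_time, c(2.5, 2))
  expect_equal(m$success_rate, 1)
  tr$t_choice[2] <- NA
  expect_message(m2 <- trial_metrics(tr), "excluded")
  expect_equal(m2$n_trials, 1)
})

test_that("session success rate recovers the programmed probability", {
  cfg <- small_cfg(trials = 100)
  cfg$learning_curve$p_success[] <- 0.8
  beh <- gen_behavior(cfg, 2, seed = 8)
  sr <- trial_metrics(beh$trials)$success_rate
  expect_lt(abs(sr - 0.8), 3 * sqrt(0.8 * 0.2 / 100))
})

test_that("running speed is the smoothed step distance over time", {
  trk <- data.frame(t = seq(0, 5, by = 0.1), x = seq(0, 50, by = 1), y = 0)
  expect_equal(running_speed(trk, sigma = 2), rep(10, nrow(trk)))
  expect_equal(running_speed(trk, sigma = 0), rep(10, nrow(trk)))
  # step change: the smoothed trace crosses the midpoint at the change
  trk2 <- data.frame(t = seq(0, 9.9, by = 0.1),
                     x = c(seq(0, 4.9, by = 0.1) * 10,
                           49 + seq(0.1, 5, by = 0.1) * 30), y = 0)
  v <- running_speed(trk2, sigma = 2)
  # the smoothed step crosses the 10 -> 30 midpoint at the change sample
  # (the finite difference places the step between samples 50 and 51)
  expect_lt(abs(mean(v[50:51]) - 20), 0.5)
  expect_error(running_speed(trk[1:2, ]), "3 tracking samples")
})

test_that("judgment metrics recover the programmed bifurcation and timing", {
  cfg <- small_cfg(trials = 40)
  cfg$trajectory_noise_sd <- 1
  cfg$traversal_cv <- 0
  cfg$learning_curve$mean_traversal[] <- 2    # constant 50 units/s
  beh <- gen_behavior(cfg, 2, seed = 13)
  s <- session(list(rat_id = "t", session_index = 2, fs_lfp = 1250,
                    fs_track = cfg$fs_track, zone_start = 0,
                    zone_length = 100), beh$trials, beh$tracking)
  jm <- judgment_metrics(s, n_perm = 1000, seed = 5)
  expect_lt(abs(jm$judgment_distance - 0.5), 0.05)
  # constant speed v = 50: time to the detected distance d is d*L/v
  expect_lt(abs(jm$judgment_time - jm$judgment_distance * 100 / 50), 0.06)
})

test_that("identical left/right trajectories yield no judgment point", {
  # left and right trials share the same centre-line trajectory
  cfg <- small_cfg(trials = 24)
  cfg$arm_separation <- 0
  beh <- gen_behavior(cfg, 1, seed = 19)
  s <- session(list(rat_id = "t", session_index = 1, fs_lfp = 1250,
                    fs_track = cfg$fs_track, zone_start = 0,
                    zone_length = 100), beh$trials, beh$tracking)
  jm <- judgment_metrics(s, n_perm = 500, seed = 2)
  expect_true(is.na(jm$judgment_distance))
  expect_true(is.na(jm$judgment_time))
})

test_that("session sets tile or slide as requested", {
  m <- data.frame(session = 1:9, success_rate = (1:9) / 10,
                  reaction_time = 9:1)
  tiled <- session_sets(m)
  expect_equal(nrow(tiled), 3)
  expect_equal(tiled$sessions, c("1,2,3", "4,5,6", "7,8,9"))
  expect_equal(tiled$success_rate, c(0.2, 0.5, 0.8))
  slid <- session_sets(m, sliding = TRUE)
  expect_equal(nrow(slid), 7)
})

test_that("Ward clustering merges the near pair first", {
  # 1-D points {0, 1, 10}: Ward increment for {0,1} is 0.5, far below any
  # merge with 10, so with k = 2 the near pair forms one cluster
  sets <- data.frame(set = 1:3, sessions = as.character(1:3),
                     success_rate = 0, reaction_time = c(0, 1, 10))
  cl <- cluster_stages(sets, k = 2, standardize = FALSE)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[1] == cl$cluster[3])
})

test_that("well-separated learning stages are recovered and ordered", {
  sets <- data.frame(set = 1:9, sessions = as.character(1:9),
                     success_rate = c(.55, .54, .56, .75, .74, .76,
                                      .93, .95, .94),
                     reaction_time = c(4.1, 4.0, 4.2, 2.9, 3.0, 2.8,
                                       1.6, 1.5, 1.7))
  cl <- cluster_stages(sets)
  expect_equal(as.character(cl$stage),
               rep(c("early", "middle", "late"), each = 3))
  # duplication leaves the partition unchanged
  cl2 <- cluster_stages(rbind(sets, sets), k = 3)
  expect_equal(as.character(cl2$stage[1:9]), as.character(cl$stage))
  expect_error(cluster_stages(sets[1:2, ], k = 3), "fewer")
})

test_that("sample skewness matches its moment definition", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_equal(sample_skewness(c(1, 2, 3, 4, 10)), 36 / 10^1.5)
  x <- rnorm(50, 2, 3)^2
  expect_equal(sample_skewness(-x), -sample_skewness(x))
  expect_error(sample_skewness(rep(3, 5)), "variance")
})

test_that("D'Agostino skewness test reproduces reference values", {
  # expected values frozen from an independent implementation of the 1970
  # Z-transformation (scipy.stats.skewtest)
  x <- c(2.1, 3.4, 1.2, 5.6, 3.3, 2.2, 8.9, 1.1, 4.5, 3.2)
  r <- dagostino_skew_test(x)
  expect_equal(r$statistic, 2.0108594288566524, tolerance = 1e-10)
  expect_equal(r$p.value, 0.044340306767134, tolerance = 1e-10)
  y <- c(0.5, 1.1, 0.3, 2.2, 0.9, 1.4, 0.7, 3.1, 0.2, 1.8, 0.6, 1.0)
  r2 <- dagostino_skew_test(y)
  expect_equal(r2$statistic, 1.865642274748802, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.062091430870242, tolerance = 1e-10)
})
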