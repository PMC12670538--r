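test_that("configuration invariants are enforced", {
  expect_error(synth_config(bifurcation_distance = 1.2), "bifurcation")
  expect_error(synth_config(coherence_4hz = 1.4), "coherence")
  expect_error(synth_config(band_4hz = c(2, 7)), "overlap")
  expect_error(synth_config(band_theta = c(6, 1000)), "inside")
  lc <- default_learning_curve(5); lc$p_success[2] <- 1.3
  expect_error(synth_config(n_sessions = 5, learning_curve = lc), "p_success")
})

test_that("noiseless trajectories coincide exactly before the bifurcation", {
  cfg <- small_cfg(trials = 20)
  cfg$trajectory_noise_sd <- 0
  beh <- gen_behavior(cfg, 2, seed = 3)
  meta <- list(rat_id = "t", session_index = 2, fs_lfp = 1250,
               fs_track = cfg$fs_track, zone_start = 0,
               zone_length = cfg$zone_length)
  s <- session(meta, beh$trials, beh$tracking)
  fam <- trajectory_family(s)
  left <- colMeans(fam$curves[fam$labels == "left", , drop = FALSE])
  right <- colMeans(fam$curves[fam$labels == "right", , drop = FALSE])
  # curves are interpolated onto bin centers from discrete tracking
  # samples, so the bin straddling the bifurcation can borrow one
  # post-divergence sample; all earlier bins must coincide exactly
  pre <- fam$positions < 0.5 - 0.03
  expect_equal(left[pre], right[pre])
  expect_gt(max(abs(left - right)[!pre]), 1)
})

test_that("perfect learners always choose the stimulus-defined arm", {
  cfg <- small_cfg(trials = 50)
  cfg$learning_curve$p_success[] <- 1
  beh <- gen_behavior(cfg, 1, seed = 5)
  expect_true(all(beh$trials$correct))
  expect_true(all(beh$trials$choice[beh$trials$stimulus == "Stim1"] == "left"))
})

test_that("constant speed and zero CV give exact traversal times", {
  cfg <- small_cfg(trials = 15)
  cfg$traversal_cv <- 0
  cfg$learning_curve$mean_traversal[] <- 2   # 100 units at 50 units/s
  beh <- gen_behavior(cfg, 1, seed = 2)
  expect_equal(beh$trials$t_exit - beh$trials$t_entry, rep(2, 15))
})

test_that("fixing the seed fixes every generated byte", {
  cfg <- small_cfg(trials = 8, n_sessions = 2)
  s1 <- simulate_session(cfg, 1, seed = 9)
  s2 <- simulate_session(cfg, 1, seed = 9)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- simulate_session(cfg, 1, seed = 10)
  expect_false(identical(s1$tracking$y, s3$tracking$y))
})

test_that("generated sessions pass the schema validator and round-trip", {
  s <- small_session()
  expect_true(validate_session(s))
  d <- withr::local_tempdir()
  write_session(s, d)
  s2 <- read_session(d)
  expect_identical(s$tracking, s2$tracking)
  expect_identical(s$trials$t_entry, s2$trials$t_entry)
  expect_identical(s$units$unit01$spike_times, s2$units$unit01$spike_times)
  expect_identical(s$lfp$pStr$samples, s2$lfp$pStr$samples)
  expect_false(is.null(attr(s2, "truth")))
})

test_that("infeasible coherence targets are rejected with a message", {
  bad <- synth_config()
  bad$coherence_4hz[] <- c(0.9, 0.9, 0)   # psd-violating pattern
  expect_error(gen_lfp(bad, 10, seed = 1), "unsolvable")
  full <- synth_config(coherence_4hz = 1)  # needs zero noise power
  expect_error(gen_lfp(full, 10, seed = 1), "unsolvable")
  expect_silent({
    ok <- synth_config(coherence_4hz = 1, noise_sd = 0)
    l <- gen_lfp(ok, 10, seed = 1)
  })
  # perfect pair: 4 Hz components identical up to scale
  b1 <- bandpass(l$regions$pStr, l$fs, c(2, 5))
  b2 <- bandpass(l$regions$dLGN, l$fs, c(2, 5))
  cc <- cor(b1$filtered, b2$filtered)
  expect_gt(abs(cc), 0.999)
})

test_that("homogeneous units recover the programmed mean rate", {
  cfg <- small_cfg(trials = 10)
  cfg$unit_specs <- unit_spec("RS", "pStr", rate = 5, tuning_amp = 0,
                              stim_gain = 1, phase_kappa = 0)
  s <- simulate_session(cfg, 1, seed = 31)
  T_total <- max(s$tracking$t)
  n <- length(s$units$unit01$spike_times)
  se <- sqrt(5 * T_total)
  expect_lt(abs(n - 5 * T_total), 3 * se)
})

test_that("phase-modulated units recover the programmed preferred phase", {
  s <- small_session()   # unit01: kappa = 2, preferred 300, ref dLGN
  bs <- bandpass(s$lfp$dLGN$samples, s$meta$fs_lfp, c(2, 5))
  ph <- spike_phases(s$units$unit01$spike_times, bs)
  expect_gt(length(ph), 200)
  mu <- Arg(sum(exp(1i * ph * pi / 180))) * 180 / pi %% 360
  expect_lt(min(abs(c(mu - 300, mu - 300 + 360, mu - 300 - 360))), 10)
})

test_that("stimulus gain doubles the judgment-zone rate ratio", {
  cfg <- small_cfg(trials = 60)
  cfg$unit_specs <- unit_spec("RS", "pStr", rate = 4, tuning_amp = 0,
                              stim_gain = 2, phase_kappa = 0)
  s <- simulate_session(cfg, 3, seed = 17)
  st <- s$units$unit01$spike_times
  zone_rate <- function(cond) {
    tr <- s$trials[s$trials$stimulus == cond, ]
    k <- sum(vapply(seq_len(nrow(tr)), function(i)
      sum(st >= tr$t_entry[i] & st < tr$t_exit[i]), numeric(1)))
    k / sum(tr$t_exit - tr$t_entry)
  }
  ratio <- zone_rate("Stim1") / zone_rate("Stim2")
  expect_lt(abs(ratio - 2), 0.45)
})

test_that("intensity ceiling rejects mis-set gains", {
  cfg <- small_cfg(trials = 8)
  cfg$unit_specs <- unit_spec("RS", "pStr", rate = 300, tuning_amp = 2,
                              stim_gain = 2, phase_kappa = 0)
  beh <- gen_behavior(cfg, 1, seed = 1)
  lfp <- gen_lfp(cfg, max(beh$tracking$t), seed = 1)
  expect_error(gen_spikes(cfg, beh, lfp, seed = 1), "ceiling")
})
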