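test_that("spike width matches the similar-triangles oracle", {
  # symmetric triangular trough, depth 60 below baseline, no after-peak,
  # total duration 0.6 ms at 40 kHz: time below -20 is 2/3 of 0.6 ms
  fs <- 40000
  tri <- c(rep(0, 20), seq(0, -60, length.out = 13),
           seq(-60, 0, length.out = 13)[-1], rep(0, 20))
  expect_equal(spike_width(tri, fs), 0.4)
  # amplitude scale invariance is exact
  expect_equal(spike_width(tri * 17.3, fs), 0.4)
  # sample duplication at doubled fs changes the width by at most one
  # sample period of the finer rate
  dup <- rep(tri, each = 2)
  expect_lt(abs(spike_width(dup, 2 * fs) - 0.4), 1000 / (2 * fs) + 1e-9)
  expect_error(spike_width(rep(1, 50), fs), "flat")
})

test_that("long-ISI proportion sums gap time over the record", {
  expect_equal(prop_long_isi(c(0, 5, 6, 7), 10), 0.5)
  expect_equal(prop_long_isi(seq(0, 99), 100), 0)
  expect_equal(prop_long_isi(c(0, 5, 6, 7), 10, threshold = Inf), 0)
  expect_warning(p <- prop_long_isi(numeric(0), 10), "2 spikes")
  expect_equal(p, 1)
})

test_that("unit classification follows the width/rate/pause rules", {
  f <- function(w, r, p, region = "pStr")
    list(spike_width = w, mean_rate = r, prop_long_isi = p, region = region)
  expect_equal(classify_unit(f(1.0, 0.5, 0.4)), "RS")
  expect_equal(classify_unit(f(0.2, 15, 0)), "FS")
  # broad never-pausing striatal unit: TAN, merged into FS by default
  expect_equal(classify_unit(f(0.9, 6, 0.01)), "FS")
  expect_equal(classify_unit(f(0.9, 6, 0.01), merge_tan = FALSE), "TAN")
  # the TAN rule is striatal: a tonic thalamic relay unit stays RS
  expect_equal(classify_unit(f(0.9, 6, 0.01, region = "dLGN")), "RS")
  # classification is invariant to waveform amplitude scaling
  w <- synth_waveform("FS")
  expect_equal(spike_width(w, attr(w, "fs")),
               spike_width(w * 3, attr(w, "fs")))
})

test_that("rate maps divide spike counts by occupancy per bin", {
  # toy session: per trial 1 s in the first zone half, 2 s in the second;
  # spikes placed 3 in the first half, 4 in the second (trial 1 only)
  sp <- c(1.0, 1.4, 1.8, 2.2, 2.6, 3.0, 3.4)
  s <- toy_session(sp)
  rm2 <- rate_map(sp, s, bins = 2)
  expect_equal(rm2$occupancy[, "pooled"], c(2, 4))
  expect_equal(rm2$counts[, "pooled"], c(3, 4))
  expect_equal(rm2$rate[, "pooled"], c(1.5, 1.0))
  # conservation: counts and occupancy are exactly the in-zone totals
  expect_equal(sum(rm2$counts[, "pooled"]), 7)
  expect_equal(sum(rm2$occupancy[, "pooled"]), 6)
  expect_equal(rm2$counts[, "Stim1"] + rm2$counts[, "Stim2"],
               rm2$counts[, "pooled"])
  # zero spikes give an all-zero map
  rm0 <- rate_map(numeric(0), s, bins = 2)
  expect_equal(rm0$rate[, "pooled"], c(0, 0))
})

test_that("spatial information reproduces its closed forms", {
  expect_equal(spatial_information(toy_rate_map(c(1, 1), c(2, 0)))$information, 1)
  expect_equal(spatial_information(toy_rate_map(c(1, 3), c(4, 0)))$information, 2)
  expect_equal(spatial_information(toy_rate_map(rep(2, 10), rep(3, 10)))$information, 0)
  # invariance under uniform rescaling of the rates
  m <- toy_rate_map(c(1, 2, 1, 4), c(0.5, 3, 1, 0.2))
  expect_equal(spatial_information(m)$information,
               spatial_information(toy_rate_map(c(1, 2, 1, 4),
                                                7 * c(0.5, 3, 1, 0.2)))$information)
  expect_error(spatial_information(toy_rate_map(c(1, 1), c(0, 0))), "zero")
})

test_that("stimulus selectivity flags a strongly gain-modulated unit", {
  s <- small_session()  # unit01 has stim_gain = 3 over 40 trials
  sel <- stimulus_selectivity(s$units$unit01$spike_times, s,
                              n_perm = 600, seed = 11)
  expect_true(sel$selective)
  # per-trial curves identical across labels can never be selective
  curves <- matrix(rep(seq(0, 1, length.out = 20), 8), 8, byrow = TRUE)
  fam <- curve_family(curves, rep(c("Stim1", "Stim2"), 4))
  expect_warning(r <- band_permutation_test(fam, exhaustive = TRUE),
                 "zero")
  expect_false(any(r$global_sig))
})

test_that("population stage averages and the early/late contrast behave", {
  set.seed(6)
  # smooth unit rate curves, as rate maps are in practice
  base <- t(replicate(12, gaussian_smooth(rnorm(30), 2) + 5))
  stages <- rep(c("early", "late"), each = 6)
  r0 <- population_stage_average(base, stages, n_perm = 400, seed = 1)
  expect_equal(dim(r0$mean), c(2, 30))
  expect_false(any(r0$early_vs_late$global_sig))
  # late-stage rate raised on the first 6 bins: significance confined
  # to a neighbourhood of that window
  up <- base; up[7:12, 1:6] <- up[7:12, 1:6] + 6
  # enough permutations that the discrete global band can reach the 5%
  # familywise level over 30 positions
  r1 <- population_stage_average(up, stages, n_perm = 2000, seed = 2)
  expect_true(any(r1$early_vs_late$global_sig[1:6]))
  expect_false(any(r1$early_vs_late$global_sig[12:30]))
  # SEM is sd/sqrt(n) per position
  expect_equal(unname(r0$sem["early", 1]),
               sd(base[1:6, 1]) / sqrt(6))
  expect_error(population_stage_average(base, rep(c("early", "late"),
                                                  c(11, 1))), ">= 2 units")
})

test_that("features of generated units recover the generator classes", {
  s <- small_session()
  total <- max(s$tracking$t)
  fe1 <- unit_features(s$units$unit01, total)
  fe2 <- unit_features(s$units$unit02, total)
  expect_equal(classify_unit(fe1), "RS")
  expect_equal(classify_unit(fe2), "FS")
  expect_gt(fe1$spike_width, 0.55)
  expect_lt(fe2$spike_width, 0.55)
})
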