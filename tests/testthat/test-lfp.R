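test_that("band-pass phase follows the cosine convention", {
  fs <- 1250
  t <- seq(0, 10, by = 1 / fs)
  bs <- bandpass(cos(2 * pi * 4 * t), fs, c(2, 5))
  mid <- seq(2501, 10000)           # away from filter edges
  peaks <- mid[abs((t[mid] * 4) %% 1) < 1e-9]
  expect_true(all(pmin(bs$phase[peaks], 360 - bs$phase[peaks]) < 2))
  troughs <- peaks + round(fs / 8)  # half a 4 Hz cycle later
  expect_true(all(abs(bs$phase[troughs] - 180) < 2))
  # amplitude scaling leaves phase unchanged, scales the envelope
  bs2 <- bandpass(3 * cos(2 * pi * 4 * t), fs, c(2, 5))
  expect_equal(bs2$phase, bs$phase, tolerance = 1e-4)
  expect_equal(bs2$amplitude, 3 * bs$amplitude, tolerance = 1e-4)
  expect_error(bandpass(rnorm(100), 100, c(2, 60)), "fs/2")
})

test_that("out-of-band tones are strongly attenuated", {
  fs <- 1250
  t <- seq(0, 10, by = 1 / fs)
  bs <- bandpass(cos(2 * pi * 20 * t), fs, c(2, 5))
  mid <- seq(2501, 10000)
  expect_lt(max(bs$amplitude[mid]), 0.05)
})

test_that("wavelet power peaks at the tone frequency and is quadratic", {
  fs <- 250
  t <- seq(0, 30, by = 1 / fs)
  p1 <- wavelet_power(sin(2 * pi * 4 * t), fs, freqs = seq(2, 10, 0.5))
  prof <- rowMeans(p1$values * ifelse(p1$valid, 1, NA), na.rm = TRUE)
  expect_equal(p1$freqs[which.max(prof)], 4, tolerance = 0.51)
  p2 <- wavelet_power(2 * sin(2 * pi * 4 * t), fs, freqs = seq(2, 10, 0.5))
  expect_equal(p2$values, 4 * p1$values, tolerance = 1e-8)
})

test_that("white-noise wavelet power is flat across frequency", {
  set.seed(3)
  fr <- c(2, 3, 4, 6, 8, 10)
  acc <- replicate(6, {
    pw <- wavelet_power(rnorm(250 * 60), 250, freqs = fr)
    vapply(seq_along(fr), function(i)
      mean(pw$values[i, pw$valid[i, ]]), numeric(1))
  })
  bm <- rowMeans(acc)
  expect_lt((max(bm) - min(bm)) / mean(bm), 0.2)
})

test_that("wavelet coherence is symmetric, bounded and exact for scaled copies", {
  set.seed(9)
  fs <- 125
  x <- striosync:::.narrowband(fs * 60, fs, c(2, 5)) + 0.3 * rnorm(fs * 60)
  wc1 <- wavelet_coherence(x, 2 * x, fs)
  expect_true(all(wc1$values[wc1$valid] > 1 - 1e-6))
  y <- rnorm(fs * 60)
  a <- wavelet_coherence(x, y, fs)
  b <- wavelet_coherence(y, x, fs)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_true(all(a$values >= 0 & a$values <= 1, na.rm = TRUE))
})

test_that("independent noise has low band coherence", {
  set.seed(14)
  fs <- 125
  a <- rnorm(fs * 600); b <- rnorm(fs * 600)
  wc <- wavelet_coherence(a, b, fs)
  expect_lt(band_mean(wc, c(2, 5)), 0.3)
})

test_that("band means respect the band, the mask and the edge cone", {
  fake <- structure(list(kind = "power", freqs = c(2, 4, 8), fs = 10,
                         values = rbind(rep(1, 10), rep(3, 10), rep(7, 10)),
                         valid = matrix(TRUE, 3, 10)),
                    class = "wavelet_map")
  expect_equal(band_mean(fake, c(2, 5)), 2)
  expect_equal(band_mean(fake, c(6, 10)), 7)
  m <- rep(c(TRUE, FALSE), 5)
  fake$values[, !m] <- 99
  expect_equal(band_mean(fake, c(2, 5), m), 2)
  expect_error(band_mean(fake, c(2, 5), rep(FALSE, 10)), "empty")
  fake$valid[] <- FALSE
  expect_error(band_mean(fake, c(2, 5)), "cone")
})

test_that("position alignment is occupancy weighted and speed invariant", {
  # two traversals of the same spatial amplitude profile at different
  # speeds: slow (4 s) then fast (2 s)
  fs_track <- 50
  mk_seg <- function(t0, dur) {
    t <- t0 + seq(0, dur - 1 / fs_track, by = 1 / fs_track)
    data.frame(t = t, x = seq(0, 99.9, length.out = length(t)), y = 0)
  }
  trk <- rbind(mk_seg(0, 4), mk_seg(4, 2))
  trials <- data.frame(trial = 1:2, stimulus = c("Stim1", "Stim2"),
                       choice = c("left", "right"), correct = TRUE,
                       t_entry = c(0, 4), t_exit = c(4, 6),
                       t_choice = c(4, 6))
  s <- session(list(rat_id = "t", session_index = 1, fs_lfp = 1000,
                    fs_track = fs_track, zone_start = 0, zone_length = 100),
               trials, trk)
  fs_sig <- 1000
  tt <- seq(0, 6, by = 1 / fs_sig)
  # amplitude decays linearly with position along the zone
  pos_of_t <- approx(trk$t, trk$x, xout = tt, rule = 2)$y / 100
  sig <- 1 - 0.8 * pos_of_t
  prof <- position_align(sig, fs_sig, s, bins = 20)
  centers <- (1:20 - 0.5) / 20
  expect_true(all(diff(prof) < 0))
  expect_equal(prof, 1 - 0.8 * centers, tolerance = 0.05)
  # each traversal alone gives the same profile (speed invariance)
  s1 <- s; s1$trials <- trials[1, ]
  s2 <- s; s2$trials <- trials[2, ]
  expect_equal(position_align(sig, fs_sig, s1, bins = 20),
               position_align(sig, fs_sig, s2, bins = 20),
               tolerance = 0.02)
  # a constant signal gives a flat profile
  expect_equal(position_align(rep(2, length(tt)), fs_sig, s, bins = 20),
               rep(2, 20))
})

test_that("Kendall tau matches pair enumeration", {
  r <- amplitude_speed_kendall(c(1, 2, 3, 4), 10, c(1, 3, 2, 4), 10)
  expect_equal(r$tau, (5 - 1) / 6, tolerance = 1e-9)
  expect_equal(amplitude_speed_kendall(1:20, 10, (1:20)^2, 10)$tau, 1)
  expect_equal(amplitude_speed_kendall(1:20, 10, rev(1:20), 10)$tau, -1)
  expect_error(amplitude_speed_kendall(rep(1, 20), 10, 1:20, 10),
               "constant")
})

test_that("theta amplitude tracks running speed; the 4 Hz band does not", {
  s <- small_session()
  sp <- running_speed(s$tracking)
  th <- bandpass(s$lfp$pStr$samples, s$meta$fs_lfp, c(6, 10))
  b4 <- bandpass(s$lfp$pStr$samples, s$meta$fs_lfp, c(2, 5))
  kt <- amplitude_speed_kendall(th$amplitude, s$meta$fs_lfp, sp,
                                s$meta$fs_track)
  k4 <- amplitude_speed_kendall(b4$amplitude, s$meta$fs_lfp, sp,
                                s$meta$fs_track)
  expect_gt(kt$tau, 0.1)
  expect_lt(kt$p.value, 0.01)
  expect_lt(abs(k4$tau), 0.1)
})

test_that("decimation preserves low-frequency content", {
  fs <- 1250
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 4 * t)
  d <- decimate_lfp(x, fs, 10)
  expect_equal(d$fs, 125)
  expect_gt(cor(d$samples[100:2000],
                sin(2 * pi * 4 * (99:1999) / 125)), 0.99)
})
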