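# Shared fixtures, built in code. The heavier ones are created lazily and
# cached for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small 3-session configuration with one tuned/selective/phase-locked RS
# unit and one FS unit
small_cfg <- function(trials = 30, n_sessions = 3, ...) {
  synth_config(
    n_sessions = n_sessions, trials_per_session = trials,
    learning_curve = default_learning_curve(n_sessions),
    unit_specs = rbind(
      unit_spec("RS", "pStr", rate = 1.2, tuning_center = 0.3,
                tuning_width = 0.12, tuning_amp = 2, stim_gain = 3,
                phase_kappa = 2, preferred_phase = 300,
                ref_region = "dLGN"),
      unit_spec("FS", "pStr", rate = 10, tuning_amp = 0.3,
                phase_kappa = 0.5, preferred_phase = 200)),
    ...)
}

# one simulated session reused by several test files
small_session <- function() {
  fixture("small_session", function()
    simulate_session(small_cfg(trials = 40), session_index = 2, seed = 104))
}

# a hand-built minimal session: 2 trials, square zone occupancy, no LFP.
# The zone is 100 units long; tracking at 10 Hz.
toy_session <- function(spike_times = numeric(0)) {
  fs <- 10
  # trial 1: 1 s in bin 1 ([0, 0.5)), 2 s in bin 2; trial 2 mirrors it
  seg <- function(t0) {
    t <- t0 + seq(0, 2.999, by = 1 / fs)
    x <- c(seq(0, 49, length.out = fs),          # 1 s in first half
           seq(50, 99, length.out = 2 * fs))     # 2 s in second half
    data.frame(t = t, x = x, y = 0)
  }
  tracking <- rbind(data.frame(t = seq(0, 0.9, by = 0.1), x = -5, y = 0),
                    seg(1), data.frame(t = seq(4, 5.9, by = 0.1), x = 120, y = 0),
                    seg(6), data.frame(t = seq(9, 9.9, by = 0.1), x = 120, y = 0))
  trials <- data.frame(trial = 1:2, stimulus = c("Stim1", "Stim2"),
                       choice = c("left", "right"), correct = c(TRUE, TRUE),
                       t_entry = c(1, 6), t_exit = c(4, 9),
                       t_choice = c(5, 9.5))
  session(list(rat_id = "toy", session_index = 1, fs_lfp = 1250,
               fs_track = fs, zone_start = 0, zone_length = 100),
          trials, tracking,
          units = if (length(spike_times))
            list(u1 = list(region = "pStr", spike_times = spike_times,
                           waveform = as.numeric(synth_waveform("RS")),
                           fs_wave = 20000)) else list(),
          lfp = list())
}

# fabricated two-bin rate map for the closed-form information cases
toy_rate_map <- function(occupancy, rate) {
  bins <- length(occupancy)
  occ <- matrix(occupancy, bins, 1, dimnames = list(NULL, "pooled"))
  r <- matrix(rate, bins, 1, dimnames = list(NULL, "pooled"))
  structure(list(centers = (seq_len(bins) - 0.5) / bins,
                 occupancy = occ, counts = r * occ, rate = r,
                 empty_bins = which(occupancy == 0)),
            class = "rate_map")
}

# independent enumeration oracle for the permutation engine: two-sided
# pointwise p at every position by brute force over all label assignments
enum_pointwise_p <- function(curves, labels) {
  lv <- levels(factor(labels))
  idxA <- which(labels == lv[1])
  n <- nrow(curves); nA <- length(idxA)
  combos <- utils::combn(n, nA, simplify = FALSE)
  obs <- colMeans(curves[idxA, , drop = FALSE]) -
    colMeans(curves[-idxA, , drop = FALSE])
  D <- t(vapply(combos, function(a)
    colMeans(curves[a, , drop = FALSE]) -
      colMeans(curves[-a, , drop = FALSE]), numeric(ncol(curves))))
  sapply(seq_len(ncol(curves)), function(j) {
    lo <- sum(D[, j] <= obs[j]); hi <- sum(D[, j] >= obs[j])
    min(1, 2 * min(lo, hi) / length(combos))
  })
}
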