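# unit-variance narrowband process: white noise band-passed with a
# forward-backward order-3 Butterworth (broadband within the band, so
# coherence and phase estimates are nondegenerate)
.narrowband <- function(n, fs, band) {
  bf <- signal::butter(3, band * 2 / fs, type = "pass")
  y <- signal::filtfilt(bf, rnorm(n))
  y / sd(y)
}

# Solve shared/private mixing weights a_r (shared amplitude) so that the
# asymptotic in-band magnitude-squared coherence of each region pair equals
# the target, accounting for the white-noise power falling inside the band.
# coh targets named c("pStr-dLGN","pStr-VC","dLGN-VC"); returns a (named by
# region) with a_r in [0,1]; errors when the implied 3x3 coherency
# structure is not realizable with one shared source.
.solve_coherence_weights <- function(coh, inband_noise) {
  regions <- c("pStr", "dLGN", "VC")
  cadj <- coh * (1 + inband_noise)^2
  pos <- cadj > 0
  a2 <- c(pStr = 0, dLGN = 0, VC = 0)
  if (all(pos)) {
    a2["pStr"] <- sqrt(cadj["pStr-dLGN"] * cadj["pStr-VC"] / cadj["dLGN-VC"])
    a2["dLGN"] <- sqrt(cadj["pStr-dLGN"] * cadj["dLGN-VC"] / cadj["pStr-VC"])
    a2["VC"]   <- sqrt(cadj["pStr-VC"] * cadj["dLGN-VC"] / cadj["pStr-dLGN"])
  } else if (!any(pos)) {
    # all independent
  } else if (sum(pos) == 1L) {
    # one coherent pair, third region independent
    pr <- names(cadj)[pos]
    both <- strsplit(pr, "-")[[1]]
    a2[both] <- sqrt(cadj[[pr]])
  } else {
    stop("unsolvable coherence targets: two positive and one zero pairwise ",
         "coherence violate the positive-semidefiniteness of the implied ",
         "3x3 coherency structure")
  }
  if (any(a2 > 1 + 1e-12))
    stop("unsolvable coherence targets: required shared power exceeds total ",
         "band power (reduce targets or noise_sd)")
  sqrt(pmin(a2, 1))
}

#' Generate three-region synthetic LFP traces
#'
#' Each region's trace is built as
#' `a_r * s4(t) + b_r * p4_r(t) + band_amp_theta * theta_r(t) * (1 +
#' theta_speed_gain * speed(t)) + noise_sd * white(t)`, all scaled by
#' `lfp_scale`: `s4` is a narrowband 2-5 Hz process shared across regions,
#' `p4_r` are independent narrowband processes, and the mixing weights are
#' solved so that the asymptotic magnitude-squared coherence of each region
#' pair inside the 4 Hz band equals the configured target. The theta
#' (6-10 Hz) processes are independent per region and their amplitude is
#' modulated by running speed.
#'
#' @param cfg A [synth_config()].
#' @param duration Trace duration in seconds.
#' @param speed Optional running-speed series (maze units/s) sampled at
#'   `speed_fs`; linearly interpolated onto the LFP clock. `NULL` means
#'   stationary (no theta-speed modulation).
#' @param speed_fs Sampling rate of `speed` (defaults to `cfg$fs_track`).
#' @param seed Optional RNG seed.
#' @return List with `regions` (named list of numeric traces, microvolts),
#'   `fs`, and `truth` (solved shared-weight vector and the target
#'   coherences).
#' @export
gen_lfp <- function(cfg, duration, speed = NULL, speed_fs = cfg$fs_track,
                    seed = NULL) {
  validate_synth_config(cfg)
  fs <- cfg$lfp_fs
  n <- round(duration * fs)
  stopifnot(n > fs)  # need at least a second
  bw <- diff(cfg$band_4hz)
  inband_noise <- cfg$noise_sd^2 * bw / (fs / 2)
  a <- .solve_coherence_weights(cfg$coherence_4hz, inband_noise)
  b <- sqrt(1 - a^2)
  regions <- c("pStr", "dLGN", "VC")

  sp <- rep(0, n)
  if (!is.null(speed)) {
    ts <- (seq_along(speed) - 1) / speed_fs
    sp <- approx(ts, speed, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  }
  with_seed(seed, {
    s4 <- .narrowband(n, fs, cfg$band_4hz)
    out <- list()
    for (r in regions) {
      p4 <- if (b[[r]] > 0) .narrowband(n, fs, cfg$band_4hz) else 0
      th <- .narrowband(n, fs, cfg$band_theta)
      wn <- if (cfg$noise_sd > 0) cfg$noise_sd * rnorm(n) else 0
      out[[r]] <- cfg$lfp_scale *
        (a[[r]] * s4 + b[[r]] * p4 +
           cfg$band_amp_theta * th * (1 + cfg$theta_speed_gain * sp) + wn)
    }
    list(regions = out, fs = fs,
         truth = list(shared_weight = a, coherence_4hz = cfg$coherence_4hz,
                      theta_speed_gain = cfg$theta_speed_gain))
  })
}
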