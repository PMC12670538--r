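#' Synthesize a mean spike waveform of a given class
#'
#' A Gaussian trough followed by a smaller after-hyperpolarization peak at
#' 25% of the trough depth. The trough Gaussian's width is chosen so the
#' trough-to-peak one-third-amplitude criterion recovers the target spike
#' width, letting downstream waveform classification recover the class.
#'
#' @param class `"RS"` (target width about 0.9 ms) or `"FS"` (about
#'   0.25 ms).
#' @param fs_wave Waveform sampling rate, Hz (default 20000).
#' @param width_ms Target width in ms; defaults by class.
#' @param amp Trough depth in microvolts.
#' @return Numeric waveform vector (4 ms window) with attribute `fs`.
#' @export
synth_waveform <- function(class = c("RS", "FS"), fs_wave = 20000,
                           width_ms = NULL, amp = 80) {
  class <- match.arg(class)
  if (is.null(width_ms)) width_ms <- if (class == "RS") 0.9 else 0.25
  p_after <- 0.25
  # half-width where the trough Gaussian crosses (1 + p)/3 of its depth
  sigma_ms <- width_ms / (2 * sqrt(2 * log(3 / (1 + p_after))))
  tms <- (seq_len(round(0.004 * fs_wave)) - 1) / fs_wave * 1000
  t0 <- 1.5
  t1 <- t0 + 4 * sigma_ms
  w <- -amp * exp(-(tms - t0)^2 / (2 * sigma_ms^2)) +
    p_after * amp * exp(-(tms - t1)^2 / (2 * sigma_ms^2))
  attr(w, "fs") <- fs_wave
  w
}

#' Generate spike trains for the configured unit population
#'
#' Each unit is an inhomogeneous point process, simulated exactly by
#' thinning of a dominating homogeneous process, with intensity
#' `lambda(t) = r0 * tuning(pos(t)) * stimgain(trial(t)) *
#' exp(kappa * cos(phi_ref(t) - phi_pref)) / I0(kappa)`.
#' Position tuning and stimulus gain act only inside the judgment zone
#' during a trial; the von Mises phase factor (normalized by the Bessel
#' function so it leaves the mean rate unchanged under uniform phase)
#' references the configured region/band oscillation.
#'
#' @param cfg A [synth_config()].
#' @param behavior Output of [gen_behavior()] (needs `trials`, `tracking`).
#' @param lfp Output of [gen_lfp()] covering the session.
#' @param seed Optional RNG seed.
#' @return Named list of units, each `list(region, spike_times, waveform,
#'   fs_wave, class)`; ground-truth parameters in attribute `"truth"`.
#' @export
gen_spikes <- function(cfg, behavior, lfp, seed = NULL) {
  validate_synth_config(cfg)
  us <- cfg$unit_specs
  trials <- behavior$trials
  trk <- behavior$tracking
  T_total <- max(trk$t)
  L <- cfg$zone_length

  # reference phases, one bandpass per (region, band) actually used
  refs <- unique(us[, c("ref_region", "ref_band")])
  phase_ref <- list()
  for (i in seq_len(nrow(refs))) {
    b <- if (refs$ref_band[i] == "4hz") cfg$band_4hz else cfg$band_theta
    bs <- bandpass(lfp$regions[[refs$ref_region[i]]], lfp$fs, b)
    phase_ref[[paste(refs$ref_region[i], refs$ref_band[i])]] <- bs$phase
  }

  with_seed(seed, {
    units <- list()
    truth <- us
    for (u in seq_len(nrow(us))) {
      s <- us[u, ]
      kap <- s$phase_kappa
      lam_max <- s$rate * (1 + s$tuning_amp) * max(s$stim_gain, 1) *
        exp(kap) / besselI(kap, 0)
      if (lam_max > cfg$rate_ceiling)
        stop("unit ", u, ": intensity ceiling exceeded (", round(lam_max),
             " Hz > ", cfg$rate_ceiling, " Hz); check gains")
      n_cand <- rpois(1, lam_max * T_total)
      cand <- sort(runif(n_cand, 0, T_total))

      # position and trial context at candidate times
      x <- approx(trk$t, trk$x, xout = cand, rule = 2)$y
      nd <- x / L
      tri <- findInterval(cand, trials$t_entry)
      in_zone <- tri >= 1 & nd >= 0 & nd <= 1
      in_zone[in_zone] <- cand[in_zone] < trials$t_exit[tri[in_zone]]
      lam <- rep(s$rate, length(cand))
      if (any(in_zone)) {
        tun <- 1 + s$tuning_amp *
          exp(-(nd[in_zone] - s$tuning_center)^2 / (2 * s$tuning_width^2))
        sg <- ifelse(trials$stimulus[tri[in_zone]] == "Stim1", s$stim_gain, 1)
        lam[in_zone] <- lam[in_zone] * tun * sg
      }
      if (kap > 0) {
        ph <- phase_ref[[paste(s$ref_region, s$ref_band)]]
        idx <- pmin(length(ph), pmax(1L, round(cand * lfp$fs) + 1L))
        lam <- lam * exp(kap * cos(deg2rad(ph[idx]) -
                                     deg2rad(s$preferred_phase))) /
          besselI(kap, 0)
      }
      keep <- runif(length(cand)) < lam / lam_max
      st <- unique(cand[keep])
      units[[sprintf("unit%02d", u)]] <- list(
        region = s$region,
        spike_times = st,
        waveform = as.numeric(synth_waveform(s$class)),
        fs_wave = 20000,
        class = s$class)
    }
    attr(units, "truth") <- truth
    units
  })
}
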