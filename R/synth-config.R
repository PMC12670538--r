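#' Specification of one synthetic unit
#'
#' @param class `"RS"` (regular-spiking, putative medium spiny neuron; low
#'   rate, broad waveform) or `"FS"` (fast-spiking, putative interneuron;
#'   high rate, narrow waveform).
#' @param region Recording region, one of `"pStr"`, `"dLGN"`, `"VC"`.
#' @param rate Baseline mean firing rate r0 in Hz.
#' @param tuning_center,tuning_width,tuning_amp Gaussian position tuning on
#'   normalized distance: inside the judgment zone the intensity is
#'   multiplied by `1 + tuning_amp * exp(-(d - center)^2 / (2 width^2))`.
#'   `tuning_amp = 0` gives flat tuning.
#' @param stim_gain Multiplicative intensity gain (>= 0) applied inside the
#'   judgment zone on Stim 1 trials; 1 means no stimulus selectivity.
#' @param phase_kappa von Mises concentration (>= 0) of spiking around the
#'   reference oscillation phase; 0 disables phase modulation.
#' @param preferred_phase Preferred firing phase in degrees (cosine
#'   convention: 0 = oscillation peak, 180 = trough).
#' @param ref_region Region whose LFP provides the reference oscillation.
#' @param ref_band Reference band, `"4hz"` or `"theta"`.
#' @return One-row data frame usable as a `unit_specs` entry.
#' @export
unit_spec <- function(class = c("RS", "FS"), region = c("pStr", "dLGN", "VC"),
                      rate = 1, tuning_center = 0.5, tuning_width = 0.15,
                      tuning_amp = 0, stim_gain = 1, phase_kappa = 0,
                      preferred_phase = 0, ref_region = "pStr",
                      ref_band = c("4hz", "theta")) {
  class <- match.arg(class); region <- match.arg(region)
  ref_band <- match.arg(ref_band)
  stopifnot(rate >= 0, tuning_width > 0, tuning_amp >= 0, stim_gain >= 0,
            phase_kappa >= 0, ref_region %in% c("pStr", "dLGN", "VC"))
  data.frame(class = class, region = region, rate = rate,
             tuning_center = tuning_center, tuning_width = tuning_width,
             tuning_amp = tuning_amp, stim_gain = stim_gain,
             phase_kappa = phase_kappa,
             preferred_phase = preferred_phase %% 360,
             ref_region = ref_region, ref_band = ref_band,
             stringsAsFactors = FALSE)
}

#' Default learning curve over training sessions
#'
#' Success probability rises sigmoidally from chance (0.5) towards 0.95 and
#' the mean judgment-zone traversal time falls from about 2.8 s to about
#' 1.2 s, emulating a one-month acquisition (about 29 sessions).
#'
#' @param n_sessions Number of sessions.
#' @return Data frame with `session`, `p_success`, `mean_traversal` (s).
#' @export
default_learning_curve <- function(n_sessions = 29) {
  s <- seq_len(n_sessions)
  mid <- n_sessions / 2.4
  g <- 1 / (1 + exp(-(s - mid) / (n_sessions / 8)))
  data.frame(session = s,
             p_success = 0.5 + 0.45 * g,
             mean_traversal = 2.8 - 1.6 * g)
}

#' Configuration of the synthetic-session generator
#'
#' Bundles all ground-truth parameters of a synthetic study: the behavioral
#' learning curve, trajectory bifurcation geometry, three-region LFP
#' oscillators with programmable 4 Hz cross-region coherence and
#' theta-amplitude/speed coupling, and the unit population.
#'
#' @param n_sessions Number of training sessions.
#' @param trials_per_session Trials per session.
#' @param learning_curve Data frame with columns `session`, `p_success`
#'   (in `[0.5, 1]`) and `mean_traversal` (s); default
#'   [default_learning_curve()].
#' @param bifurcation_distance Normalized distance in (0, 1) at which left-
#'   and right-choice trajectories start to diverge.
#' @param trajectory_noise_sd SD of the (temporally smoothed) lateral
#'   tracking noise, maze units.
#' @param arm_separation Lateral separation of the two choice trajectories
#'   at the end of the judgment zone, maze units.
#' @param speed_profile Multiplicative running-speed shape over
#'   normalized-distance bins (mean 1); a flat profile by default.
#' @param traversal_cv Coefficient of variation of the log-normal
#'   trial-to-trial traversal duration (default 0.18, matching the
#'   observed 17.7% CV of zone traversal time).
#' @param zone_length Judgment-zone length in maze units.
#' @param port_run Distance from the zone exit to the reward port.
#' @param fs_track Tracking sampling rate, Hz.
#' @param lfp_fs LFP sampling rate, Hz (default 1250).
#' @param band_4hz,band_theta Band edges in Hz (defaults `[2, 5]` and
#'   `[6, 10]`); must not overlap and must lie inside `(0, lfp_fs / 2)`.
#' @param coherence_4hz Target pairwise magnitude-squared coherence of the
#'   4 Hz component, a single value or a named vector over
#'   `c("pStr-dLGN", "pStr-VC", "dLGN-VC")`, each in `[0, 1]`.
#' @param theta_speed_gain Theta amplitude gain per unit running speed.
#' @param band_amp_theta Theta amplitude relative to the 4 Hz component.
#' @param noise_sd Broadband white-noise SD relative to the unit-variance
#'   band-limited processes.
#' @param lfp_scale Overall LFP scale in microvolts.
#' @param unit_specs Data frame of [unit_spec()] rows.
#' @param rate_ceiling Hard ceiling on the instantaneous intensity, Hz;
#'   mis-set gains that exceed it are rejected.
#' @return Validated object of class `synth_config`.
#' @export
synth_config <- function(n_sessions = 29,
                         trials_per_session = 60,
                         learning_curve = default_learning_curve(n_sessions),
                         bifurcation_distance = 0.5,
                         trajectory_noise_sd = 1.5,
                         arm_separation = 50,
                         speed_profile = rep(1, 50),
                         traversal_cv = 0.18,
                         zone_length = 100,
                         port_run = 60,
                         fs_track = 50,
                         lfp_fs = 1250,
                         band_4hz = c(2, 5),
                         band_theta = c(6, 10),
                         coherence_4hz = 0.3,
                         theta_speed_gain = 0.02,
                         band_amp_theta = 0.7,
                         noise_sd = 0.5,
                         lfp_scale = 50,
                         unit_specs = default_unit_specs(),
                         rate_ceiling = 500) {
  pairs <- c("pStr-dLGN", "pStr-VC", "dLGN-VC")
  if (length(coherence_4hz) == 1L) {
    coherence_4hz <- rep(coherence_4hz, 3L)
    names(coherence_4hz) <- pairs
  }
  if (!all(pairs %in% names(coherence_4hz)))
    stop("coherence_4hz must be a single value or named over: ",
         paste(pairs, collapse = ", "))
  coherence_4hz <- coherence_4hz[pairs]

  cfg <- structure(list(
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    learning_curve = learning_curve,
    bifurcation_distance = bifurcation_distance,
    trajectory_noise_sd = trajectory_noise_sd,
    arm_separation = arm_separation,
    speed_profile = speed_profile,
    traversal_cv = traversal_cv,
    zone_length = zone_length,
    port_run = port_run,
    fs_track = fs_track,
    lfp_fs = lfp_fs,
    band_4hz = band_4hz,
    band_theta = band_theta,
    coherence_4hz = coherence_4hz,
    theta_speed_gain = theta_speed_gain,
    band_amp_theta = band_amp_theta,
    noise_sd = noise_sd,
    lfp_scale = lfp_scale,
    unit_specs = unit_specs,
    rate_ceiling = rate_ceiling
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @param cfg A `synth_config` object.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  bad <- character(0)
  lc <- cfg$learning_curve
  if (!all(c("session", "p_success", "mean_traversal") %in% names(lc)))
    bad <- c(bad, "learning_curve must have session, p_success, mean_traversal")
  else {
    if (nrow(lc) < cfg$n_sessions)
      bad <- c(bad, "learning_curve shorter than n_sessions")
    if (any(lc$p_success < 0 | lc$p_success > 1))
      bad <- c(bad, "p_success outside [0, 1]")
    if (any(lc$mean_traversal <= 0))
      bad <- c(bad, "mean_traversal must be positive")
  }
  if (!(cfg$bifurcation_distance > 0 && cfg$bifurcation_distance < 1))
    bad <- c(bad, "bifurcation_distance outside (0, 1)")
  if (cfg$trajectory_noise_sd < 0) bad <- c(bad, "trajectory_noise_sd < 0")
  if (any(cfg$coherence_4hz < 0 | cfg$coherence_4hz > 1))
    bad <- c(bad, "coherence_4hz outside [0, 1]")
  nyq <- cfg$lfp_fs / 2
  for (b in list(cfg$band_4hz, cfg$band_theta)) {
    if (length(b) != 2 || b[1] <= 0 || b[2] >= nyq || b[1] >= b[2])
      bad <- c(bad, "bands must be increasing and inside (0, lfp_fs/2)")
  }
  if (length(bad) == 0 && cfg$band_4hz[2] > cfg$band_theta[1] &&
      cfg$band_theta[2] > cfg$band_4hz[1])
    bad <- c(bad, "band_4hz and band_theta overlap")
  us <- cfg$unit_specs
  if (nrow(us) > 0) {
    if (any(us$rate < 0)) bad <- c(bad, "unit rates must be >= 0")
    if (any(us$phase_kappa < 0)) bad <- c(bad, "phase_kappa must be >= 0")
    if (any(us$stim_gain < 0)) bad <- c(bad, "stim_gain must be >= 0")
  }
  if (abs(mean(cfg$speed_profile) - 1) > 0.05)
    bad <- c(bad, "speed_profile must have mean ~1 (it is a shape)")
  if (length(bad)) stop("invalid synth_config: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

#' @rdname unit_spec
#' @export
default_unit_specs <- function() {
  rbind(
    unit_spec("RS", "pStr", rate = 1.2, tuning_center = 0.2,
              tuning_width = 0.12, tuning_amp = 2, stim_gain = 1.5,
              phase_kappa = 1, preferred_phase = 180, ref_region = "pStr"),
    unit_spec("RS", "pStr", rate = 0.8, tuning_center = 0.6,
              tuning_width = 0.15, tuning_amp = 1.5, stim_gain = 1,
              phase_kappa = 0.8, preferred_phase = 300, ref_region = "dLGN"),
    unit_spec("FS", "pStr", rate = 10, tuning_amp = 0.3, tuning_center = 0.5,
              tuning_width = 0.2, stim_gain = 1, phase_kappa = 0.4,
              preferred_phase = 200, ref_region = "pStr"),
    unit_spec("RS", "dLGN", rate = 4, tuning_amp = 0.5, tuning_center = 0.4,
              tuning_width = 0.2, stim_gain = 2, phase_kappa = 0.6,
              preferred_phase = 300, ref_region = "dLGN"),
    unit_spec("RS", "VC", rate = 2, tuning_amp = 0.5, tuning_center = 0.5,
              tuning_width = 0.2, stim_gain = 1.8, phase_kappa = 0.5,
              preferred_phase = 300, ref_region = "VC")
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_sessions, "sessions x", x$trials_per_session,
      "trials;", nrow(x$unit_specs), "units\n")
  cat(sprintf("  bifurcation at %.2f, 4 Hz coherence targets: %s\n",
              x$bifurcation_distance,
              paste(sprintf("%s=%.2f", names(x$coherence_4hz),
                            x$coherence_4hz), collapse = ", ")))
  invisible(x)
}
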