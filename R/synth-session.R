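#' Simulate one complete synthetic session
#'
#' Chains [gen_behavior()], [gen_lfp()] (theta amplitude modulated by the
#' session's own running speed) and [gen_spikes()] into a validated
#' [session()] container with the ground truth attached as attribute
#' `"truth"`.
#'
#' @param cfg A [synth_config()].
#' @param session_index Session of the learning curve to simulate.
#' @param seed RNG seed; one seed fixes every generated value.
#' @param rat_id Identifier stored in the session metadata.
#' @return A `maze_session` with attribute `"truth"`.
#' @export
simulate_session <- function(cfg, session_index = 1, seed = 1,
                             rat_id = "synth01") {
  with_seed(seed, {
    beh <- gen_behavior(cfg, session_index)
    speed <- running_speed(beh$tracking, sigma = 2)
    lfp <- gen_lfp(cfg, duration = max(beh$tracking$t), speed = speed,
                   speed_fs = cfg$fs_track)
    units <- gen_spikes(cfg, beh, lfp)
    meta <- list(rat_id = rat_id, session_index = session_index,
                 fs_lfp = cfg$lfp_fs, fs_track = cfg$fs_track,
                 zone_start = 0, zone_length = cfg$zone_length)
    s <- session(meta, beh$trials, beh$tracking, units,
                 lapply(lfp$regions, function(v) list(samples = v,
                                                      fs = lfp$fs)))
    third <- ceiling(cfg$n_sessions / 3)
    attr(s, "truth") <- list(
      behavior = beh$truth,
      lfp = lfp$truth,
      units = attr(units, "truth"),
      stage = c("early", "middle", "late")[
        pmin(3, (session_index - 1) %/% third + 1)])
    s
  })
}

#' Simulate a multi-session synthetic study
#'
#' @param cfg A [synth_config()].
#' @param seed Base seed; session `i` uses `seed + 7919 * i`.
#' @param sessions Session indices to simulate (default all).
#' @param rat_id Identifier for the synthetic subject.
#' @return List of `maze_session` objects.
#' @export
simulate_study <- function(cfg, seed = 1, sessions = seq_len(cfg$n_sessions),
                           rat_id = "synth01") {
  lapply(sessions, function(i)
    simulate_session(cfg, i, seed = (seed + 7919 * i) %% .Machine$integer.max,
                     rat_id = rat_id))
}
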