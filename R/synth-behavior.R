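#' Generate behavior (trials and head tracking) for one synthetic session
#'
#' Trials draw an equiprobable stimulus (Stim 1 -> left arm rewarded,
#' Stim 2 -> right); the choice matches the correct arm with the session's
#' programmed success probability. Judgment-zone traversal durations are
#' log-normal around the session mean (programmable CV). Head trajectories
#' run straight down the zone mid-line and, beyond the bifurcation
#' distance, diverge linearly towards the chosen arm; temporally smoothed
#' Gaussian noise is added to the lateral coordinate. Between trials the
#' animal glides from the reward port back to the zone entrance, so speed
#' is finite everywhere.
#'
#' @param cfg A [synth_config()].
#' @param session_index Which session of the learning curve to generate.
#' @param seed Optional RNG seed.
#' @return List with `trials` (data frame: trial, stimulus, choice,
#'   correct, t_entry, t_exit, t_choice), `tracking` (data frame: t, x, y
#'   at `fs_track`), and `truth` (programmed parameters).
#' @export
gen_behavior <- function(cfg, session_index = 1, seed = NULL) {
  validate_synth_config(cfg)
  d0 <- cfg$bifurcation_distance
  if (!(d0 > 0 && d0 < 1)) stop("bifurcation_distance outside (0, 1)")
  lc <- cfg$learning_curve[cfg$learning_curve$session == session_index, ]
  if (nrow(lc) != 1) stop("session_index not in learning_curve")
  with_seed(seed, {
    nt <- cfg$trials_per_session
    L <- cfg$zone_length
    stimulus <- sample(c("Stim1", "Stim2"), nt, replace = TRUE)
    correct_arm <- ifelse(stimulus == "Stim1", "left", "right")
    success <- runif(nt) < lc$p_success
    choice <- ifelse(success, correct_arm,
                     ifelse(correct_arm == "left", "right", "left"))
    cv <- cfg$traversal_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      tt <- rlnorm(nt, meanlog = log(lc$mean_traversal) - sdlog^2 / 2,
                   sdlog = sdlog)
    } else tt <- rep(lc$mean_traversal, nt)

    # event times: entry -> exit (zone) -> choice (reward-port arrival)
    v_bar <- L / tt
    t_port <- cfg$port_run / v_bar
    gap <- runif(nt, 4, 8)
    t_entry <- t_exit <- t_choice <- numeric(nt)
    t0 <- 5
    for (i in seq_len(nt)) {
      t_entry[i] <- t0
      t_exit[i] <- t_entry[i] + tt[i]
      t_choice[i] <- t_exit[i] + t_port[i]
      t0 <- t_choice[i] + gap[i]
    }
    trials <- data.frame(trial = seq_len(nt), stimulus = stimulus,
                         choice = choice, correct = choice == correct_arm,
                         t_entry = t_entry, t_exit = t_exit,
                         t_choice = t_choice, stringsAsFactors = FALSE)

    # waypoints (t, x, y) interpolated onto the uniform tracking grid
    nbin <- length(cfg$speed_profile)
    wt <- (1 / cfg$speed_profile); wt <- wt / sum(wt)  # time share per bin
    nd_dense <- seq(0, 1, length.out = 200)
    # cumulative traversal-time fraction at nd_dense
    cum_wt <- c(0, cumsum(wt))
    frac_at <- function(nd) {
      b <- pmin(nbin, floor(nd * nbin) + 1)
      cum_wt[b] + (nd * nbin - (b - 1)) * wt[b]
    }
    tfrac <- frac_at(nd_dense)

    wp_t <- wp_x <- wp_y <- list()
    arm_sign <- ifelse(trials$choice == "right", 1, -1)
    y_dev <- function(nd, s) ifelse(nd <= d0, 0,
      s * cfg$arm_separation / 2 * (nd - d0) / (1 - d0))
    for (i in seq_len(nt)) {
      tz <- t_entry[i] + tfrac * tt[i]
      xz <- nd_dense * L
      yz <- y_dev(nd_dense, arm_sign[i])
      y_port <- arm_sign[i] * (cfg$arm_separation / 2 + 20)
      t_dwell <- t_choice[i] + min(1.2, gap[i] / 3)
      wp_t[[i]] <- c(tz, t_choice[i], t_dwell)
      wp_x[[i]] <- c(xz, L + cfg$port_run, L + cfg$port_run)
      wp_y[[i]] <- c(yz, y_port, y_port)
    }
    wt_all <- c(0, unlist(wp_t), t_choice[nt] + gap[nt])
    wx_all <- c(0, unlist(wp_x), 0)
    wy_all <- c(0, unlist(wp_y), 0)

    tgrid <- seq(0, max(wt_all), by = 1 / cfg$fs_track)
    x <- approx(wt_all, wx_all, xout = tgrid, rule = 2)$y
    y <- approx(wt_all, wy_all, xout = tgrid, rule = 2)$y
    if (cfg$trajectory_noise_sd > 0) {
      e <- gaussian_smooth(rnorm(length(tgrid)), sigma = 0.12 * cfg$fs_track)
      y <- y + e * cfg$trajectory_noise_sd / sd(e)
    }
    tracking <- data.frame(t = tgrid, x = x, y = y)
    list(trials = trials, tracking = tracking,
         truth = list(bifurcation_distance = d0,
                      p_success = lc$p_success,
                      mean_traversal = lc$mean_traversal,
                      session_index = session_index))
  })
}
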