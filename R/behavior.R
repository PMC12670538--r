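#' Per-trial behavioral metrics and session summary
#'
#' Reaction time is the latency from judgment-zone entry to arrival at the
#' reward port (`t_choice - t_entry`); the success rate is the fraction of
#' correct trials. Trials with missing timestamps are excluded with a
#' message.
#'
#' @param trials Trials data frame (see [session()]).
#' @return List with `per_trial` (trial, reaction_time, correct),
#'   `success_rate`, `reaction_time_median`, `reaction_time_mean`, and
#'   `n_trials` actually used.
#' @export
trial_metrics <- function(trials) {
  ok <- complete.cases(trials[, c("t_entry", "t_choice", "correct")])
  if (any(!ok))
    message(sum(!ok), " trial(s) excluded for missing timestamps")
  tr <- trials[ok, ]
  rt <- tr$t_choice - tr$t_entry
  list(per_trial = data.frame(trial = tr$trial, reaction_time = rt,
                              correct = tr$correct),
       success_rate = mean(tr$correct),
       reaction_time_median = median(rt),
       reaction_time_mean = mean(rt),
       n_trials = nrow(tr))
}

#' Instantaneous running speed from head tracking
#'
#' Per-step travel distance divided by the time step, then smoothed with a
#' Gaussian kernel (default sigma of 2 samples). `sigma = 0` returns the
#' raw finite-difference speed.
#'
#' @param tracking Data frame with `t`, `x`, `y` (uniformly sampled).
#' @param sigma Gaussian kernel SD in samples.
#' @return Speed series (maze units/s), same length as the tracking.
#' @export
running_speed <- function(tracking, sigma = 2) {
  if (nrow(tracking) < 3) stop("need at least 3 tracking samples")
  dt <- diff(tracking$t)
  d <- sqrt(diff(tracking$x)^2 + diff(tracking$y)^2)
  v <- d / dt
  v <- c(v[1], v)  # pad to input length
  gaussian_smooth(v, sigma)
}

#' Per-trial lateral-position curves over the judgment zone
#'
#' Interpolates each trial's lateral coordinate onto a common
#' normalized-distance grid and labels trials by the chosen arm, producing
#' the [curve_family()] whose left/right divergence defines the judgment
#' point.
#'
#' @param s A [session()].
#' @param bins Number of normalized-distance bins (default 50; half-open
#'   bins, last bin closed).
#' @return A `curve_family` (labels = choice).
#' @export
trajectory_family <- function(s, bins = 50) {
  centers <- (seq_len(bins) - 0.5) / bins
  tr <- s$trials
  if (sum(tr$choice == "left") < 2 || sum(tr$choice == "right") < 2)
    stop("need at least 2 left-choice and 2 right-choice trials")
  curves <- matrix(NA_real_, nrow(tr), bins)
  for (i in seq_len(nrow(tr))) {
    sel <- s$tracking$t >= tr$t_entry[i] & s$tracking$t < tr$t_exit[i]
    nd <- normalized_distance(s, s$tracking$x[sel])
    y <- s$tracking$y[sel]
    o <- order(nd)
    curves[i, ] <- approx(nd[o], y[o], xout = centers, rule = 2, ties = mean)$y
  }
  curve_family(curves, tr$choice, positions = centers)
}

#' Judgment distance and judgment time of one session
#'
#' The judgment distance is the earliest normalized distance at which the
#' left- and right-choice trajectories differ significantly under the
#' globally corrected permutation-band test; the judgment time is the
#' median latency from zone entry to first crossing of that distance.
#'
#' @param s A [session()].
#' @param bins Normalized-distance bins.
#' @param n_perm,alpha,seed Passed to [band_permutation_test()].
#' @param k_run Contiguity run length for [first_divergence()].
#' @return List with `judgment_distance`, `judgment_time` (both `NA` when
#'   no divergence is found) and the underlying `band_perm_result`.
#' @export
judgment_metrics <- function(s, bins = 50, n_perm = 1000, alpha = 0.05,
                             seed = NULL, k_run = 3) {
  fam <- trajectory_family(s, bins)
  res <- band_permutation_test(fam, n_perm = n_perm, alpha = alpha,
                               seed = seed)
  jd <- first_divergence(res, k_run = k_run)
  jt <- NA_real_
  if (!is.na(jd)) {
    lat <- vapply(seq_len(nrow(s$trials)), function(i) {
      sel <- s$tracking$t >= s$trials$t_entry[i] &
        s$tracking$t < s$trials$t_exit[i]
      nd <- normalized_distance(s, s$tracking$x[sel])
      tt <- s$tracking$t[sel]
      hit <- which(nd >= jd)
      if (length(hit)) tt[hit[1]] - s$trials$t_entry[i] else NA_real_
    }, numeric(1))
    jt <- median(lat, na.rm = TRUE)
  }
  list(judgment_distance = jd, judgment_time = jt, result = res)
}

#' Aggregate sessions into consecutive session sets
#'
#' Learning-stage clustering operates on consecutive sets of three
#' sessions. Disjoint tiling is the default; `sliding = TRUE` uses every
#' consecutive window instead.
#'
#' @param metrics Data frame with one row per session: `session`,
#'   `success_rate`, `reaction_time`.
#' @param width Sessions per set (default 3).
#' @param sliding Overlapping windows instead of disjoint triplets.
#' @return Data frame: `set`, `sessions` (comma-joined), `success_rate`,
#'   `reaction_time` (set means).
#' @export
session_sets <- function(metrics, width = 3, sliding = FALSE) {
  stopifnot(all(c("session", "success_rate", "reaction_time") %in%
                  names(metrics)))
  metrics <- metrics[order(metrics$session), ]
  n <- nrow(metrics)
  starts <- if (sliding) seq_len(n - width + 1) else seq(1, n - width + 1,
                                                         by = width)
  do.call(rbind, lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + width - 1)
    data.frame(set = k,
               sessions = paste(metrics$session[idx], collapse = ","),
               success_rate = mean(metrics$success_rate[idx]),
               reaction_time = mean(metrics$reaction_time[idx]))
  }))
}

#' Learning-stage assignment by Ward clustering of behavioral features
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance) of session
#' sets on success rate and reaction time, cut at `k` clusters. Features
#' are z-scored by default because the two are incommensurate (a
#' proportion vs seconds). Stages are ordered behaviorally, not by
#' dendrogram order: the slowest cluster (highest mean reaction time) is
#' `early`, the fastest is `late`.
#'
#' @param sets Data frame from [session_sets()].
#' @param k Number of stages (default 3).
#' @param standardize z-score each feature before clustering.
#' @return `sets` with added `cluster` (raw cut) and `stage` (ordered
#'   factor `early < middle < late` for `k = 3`, `stage1..k` otherwise).
#' @export
cluster_stages <- function(sets, k = 3, standardize = TRUE) {
  if (nrow(sets) < k) stop("fewer session sets (", nrow(sets),
                           ") than clusters (", k, ")")
  X <- as.matrix(sets[, c("success_rate", "reaction_time")])
  if (!all(is.finite(X))) stop("non-finite features")
  if (standardize) {
    X <- scale(X)
    X[, apply(is.na(X), 2, all)] <- 0  # zero-variance feature
    X[is.na(X)] <- 0
  }
  hc <- hclust(dist(X), method = "ward.D2")
  cl <- cutree(hc, k = k)
  rt_by_cl <- tapply(sets$reaction_time, cl, mean)
  ord <- order(rt_by_cl, decreasing = TRUE)  # slowest first = earliest
  stage_names <- if (k == 3) c("early", "middle", "late")
                 else paste0("stage", seq_len(k))
  stage_of <- stage_names[match(cl, ord)]
  sets$cluster <- cl
  sets$stage <- factor(stage_of, levels = stage_names, ordered = TRUE)
  sets
}

#' Moment sample skewness
#'
#' `g1 = m3 / m2^(3/2)` with central moments `m2`, `m3`; the statistic
#' whose decline across learning stages indexes the symmetrization of the
#' reaction-time distribution.
#'
#' @param x Numeric sample, `n >= 3`.
#' @return Skewness `g1`.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  mean((x - m)^3) / m2^1.5
}

#' D'Agostino test of skewness
#'
#' Two-sided test of symmetry based on the normalizing Z-transformation of
#' the sample skewness (D'Agostino 1970).
#'
#' @param x Numeric sample, `n >= 8` for the approximation to hold.
#' @return List with `skewness`, `statistic` (Z), `p.value`.
#' @export
dagostino_skew_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need n >= 8")
  g1 <- sample_skewness(x)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  list(skewness = g1, statistic = Z, p.value = 2 * pnorm(-abs(Z)))
}
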