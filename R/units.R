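#' Spike width from a mean waveform
#'
#' Width is the contiguous duration around the trough during which the
#' waveform stays more than one third of the trough-to-peak amplitude
#' below baseline (pre-trough median). The two threshold crossings are
#' located with linear sub-sample interpolation, so the measure is
#' independent of amplitude scaling and, up to one sample period, of the
#' sampling rate.
#'
#' @param waveform Numeric voltage vector with a unique global trough.
#' @param fs Waveform sampling rate, Hz.
#' @return Width in ms.
#' @export
spike_width <- function(waveform, fs) {
  w <- as.numeric(waveform)
  if (length(unique(w)) < 2) stop("flat waveform: width undefined")
  tr <- which.min(w)
  if (tr < 2) stop("trough at the first sample: no pre-trough baseline")
  baseline <- median(w[seq_len(tr - 1)])
  peak <- max(w[tr:length(w)])
  level <- baseline - (peak - w[tr]) / 3
  if (w[tr] >= level) stop("trough does not reach the one-third level")
  # walk outwards from the trough to the last samples below the level
  i <- tr; while (i > 1 && w[i - 1] < level) i <- i - 1
  j <- tr; while (j < length(w) && w[j + 1] < level) j <- j + 1
  # sub-sample crossings
  t_left <- if (i == 1) i else i - (level - w[i]) / (w[i - 1] - w[i])
  t_right <- if (j == length(w)) j else j + (level - w[j]) / (w[j + 1] - w[j])
  (t_right - t_left) * 1000 / fs
}

#' Proportion of recording time in long inter-spike intervals
#'
#' Sums ISIs strictly longer than `threshold` and divides by the total
#' recording time; low values characterize tonically active neurons.
#' With fewer than 2 spikes the whole record is one long gap and 1.0 is
#' returned with a warning.
#'
#' @param spike_times Sorted spike times, s.
#' @param total_time Total recording time, s (> 0).
#' @param threshold ISI threshold, s (default 2).
#' @return Proportion in `[0, 1]`.
#' @export
prop_long_isi <- function(spike_times, total_time, threshold = 2) {
  stopifnot(total_time > 0)
  if (length(spike_times) < 2) {
    warning("fewer than 2 spikes: whole record treated as one long gap")
    return(1.0)
  }
  isi <- diff(spike_times)
  min(1, sum(isi[isi > threshold]) / total_time)
}

#' Waveform and firing-statistics features of one unit
#'
#' @param u A unit entry of a [session()] (`region`, `spike_times`,
#'   `waveform`, `fs_wave`).
#' @param total_time Session duration, s.
#' @return Data frame row: `region`, `spike_width` (ms), `mean_rate` (Hz,
#'   whole session), `prop_long_isi`.
#' @export
unit_features <- function(u, total_time) {
  data.frame(region = u$region,
             spike_width = spike_width(u$waveform, u$fs_wave),
             mean_rate = length(u$spike_times) / total_time,
             prop_long_isi = suppressWarnings(
               prop_long_isi(u$spike_times, total_time)),
             stringsAsFactors = FALSE)
}

#' Rule-based RS/FS/TAN unit classification
#'
#' Fast-spiking (FS, putative PV interneurons): narrow waveform and high
#' rate. Tonically active neurons (TAN, putative cholinergic): broad
#' waveform that almost never pauses (low long-ISI proportion); a striatal
#' cell class, so the TAN rule is applied only to pStr units, and TANs are
#' grouped with FS by default, mirroring the small-TAN-count pooling used
#' for population analyses. Everything else is regular-spiking (RS,
#' putative medium spiny neurons in the striatum, putative excitatory
#' neurons elsewhere). Boundary values are free parameters exposed as
#' arguments.
#'
#' @param features One-row data frame from [unit_features()] (or any list
#'   with `spike_width`, `mean_rate`, `prop_long_isi`, and optionally
#'   `region`).
#' @param w0 Spike-width boundary, ms (default 0.55).
#' @param r0 Rate boundary, Hz (default 2).
#' @param p0 Long-ISI proportion boundary (default 0.05).
#' @param merge_tan Report TANs as FS (default `TRUE`).
#' @return Label: `"RS"`, `"FS"`, or `"TAN"` (only when
#'   `merge_tan = FALSE`).
#' @export
classify_unit <- function(features, w0 = 0.55, r0 = 2, p0 = 0.05,
                          merge_tan = TRUE) {
  width <- features$spike_width; rate <- features$mean_rate
  pli <- features$prop_long_isi
  striatal <- is.null(features$region) || features$region == "pStr"
  label <-
    if (width < w0 && rate >= r0) "FS"
    else if (striatal && width >= w0 && pli < p0) "TAN"
    else "RS"
  if (label == "TAN" && merge_tan) label <- "FS"
  label
}

#' Occupancy-normalized firing-rate map over the judgment zone
#'
#' For each normalized-distance bin (half-open `[i/bins, (i+1)/bins)`,
#' last bin closed) and condition, the rate is the number of spikes
#' emitted while the animal was in that bin divided by the time spent
#' there. Spikes are assigned to the animal's bin at spike time (nearest
#' tracking sample). Bins with zero occupancy are `NA` and flagged.
#'
#' @param spike_times Unit spike times, s.
#' @param s A [session()].
#' @param bins Number of bins (default 50).
#' @param by_stimulus Also split by Stim 1 / Stim 2 (default `TRUE`).
#' @param smooth_sd Optional Gaussian smoothing of the rate curves, in
#'   bins (default 0, none).
#' @return Object of class `rate_map`: `centers`, `occupancy`, `counts`,
#'   `rate` (bins x conditions matrices, conditions `pooled`, `Stim1`,
#'   `Stim2`), and `empty_bins`.
#' @export
rate_map <- function(spike_times, s, bins = 50, by_stimulus = TRUE,
                     smooth_sd = 0) {
  conds <- if (by_stimulus) c("pooled", "Stim1", "Stim2") else "pooled"
  occ <- cnt <- matrix(0, bins, length(conds),
                       dimnames = list(NULL, conds))
  dt <- 1 / s$meta$fs_track
  tr <- s$trials
  trk <- s$tracking
  for (i in seq_len(nrow(tr))) {
    sel <- which(trk$t >= tr$t_entry[i] & trk$t < tr$t_exit[i])
    if (!length(sel)) next
    nd <- normalized_distance(s, trk$x[sel])
    b <- pmin(bins, pmax(1L, floor(nd * bins) + 1L))
    occ_i <- tabulate(b, bins) * dt
    sp <- spike_times[spike_times >= tr$t_entry[i] &
                        spike_times < tr$t_exit[i]]
    bsp <- integer(0)
    if (length(sp)) {
      near <- sel[pmax(1L, pmin(length(sel),
                                round((sp - trk$t[sel[1]]) * s$meta$fs_track) + 1L))]
      ndsp <- normalized_distance(s, trk$x[near])
      bsp <- pmin(bins, pmax(1L, floor(ndsp * bins) + 1L))
    }
    cnt_i <- tabulate(bsp, bins)
    use <- "pooled"
    if (by_stimulus) use <- c("pooled", tr$stimulus[i])
    for (cc in use) {
      occ[, cc] <- occ[, cc] + occ_i
      cnt[, cc] <- cnt[, cc] + cnt_i
    }
  }
  rate <- cnt / occ
  rate[occ == 0] <- NA_real_
  if (smooth_sd > 0)
    for (cc in seq_len(ncol(rate))) {
      v <- rate[, cc]
      if (!anyNA(v)) rate[, cc] <- gaussian_smooth(v, smooth_sd)
    }
  structure(list(centers = (seq_len(bins) - 0.5) / bins,
                 occupancy = occ, counts = cnt, rate = rate,
                 empty_bins = which(occ[, "pooled"] == 0)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %d bins, %d spikes pooled, %.1f s occupancy, %d empty bin(s)\n",
              length(x$centers), sum(x$counts[, "pooled"]),
              sum(x$occupancy[, "pooled"]), length(x$empty_bins)))
  invisible(x)
}

#' Per-trial firing-rate curves over the judgment zone
#'
#' One rate curve per trial (spike count over time in bin, per bin);
#' unvisited bins within a trial are filled by linear interpolation along
#' the curve so the result is a valid [curve_family()] input.
#'
#' @inheritParams rate_map
#' @return Matrix, trials x bins, with the trial order of the session.
#' @export
trial_rate_curves <- function(spike_times, s, bins = 50) {
  dt <- 1 / s$meta$fs_track
  tr <- s$trials
  trk <- s$tracking
  out <- matrix(NA_real_, nrow(tr), bins)
  for (i in seq_len(nrow(tr))) {
    sel <- which(trk$t >= tr$t_entry[i] & trk$t < tr$t_exit[i])
    if (!length(sel)) next
    nd <- normalized_distance(s, trk$x[sel])
    b <- pmin(bins, pmax(1L, floor(nd * bins) + 1L))
    occ_i <- tabulate(b, bins) * dt
    sp <- spike_times[spike_times >= tr$t_entry[i] &
                        spike_times < tr$t_exit[i]]
    bsp <- integer(0)
    if (length(sp)) {
      near <- sel[pmax(1L, pmin(length(sel),
                                round((sp - trk$t[sel[1]]) * s$meta$fs_track) + 1L))]
      bsp <- pmin(bins, pmax(1L, floor(normalized_distance(s, trk$x[near]) *
                                         bins) + 1L))
    }
    v <- tabulate(bsp, bins) / occ_i
    v[occ_i == 0] <- NA_real_
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      if (length(ok) >= 2)
        v <- approx(ok, v[ok], xout = seq_len(bins), rule = 2)$y
      else v[is.na(v)] <- 0
    }
    out[i, ] <- v
  }
  out
}

#' Stimulus selectivity of one unit by the permutation-band test
#'
#' Builds per-trial rate curves, compares Stim 1 vs Stim 2 with
#' [band_permutation_test()], and flags the unit selective when any
#' position is significant under the globally corrected band (the
#' familywise-safe mask; the pointwise mask is also available in the
#' returned result).
#'
#' @inheritParams rate_map
#' @param n_perm,alpha,seed Passed to [band_permutation_test()].
#' @return List with `selective` (logical), `n_sig_positions`, and the
#'   `band_perm_result`.
#' @export
stimulus_selectivity <- function(spike_times, s, bins = 50, n_perm = 1000,
                                 alpha = 0.05, seed = NULL) {
  curves <- trial_rate_curves(spike_times, s, bins)
  fam <- curve_family(curves, s$trials$stimulus)
  res <- band_permutation_test(fam, n_perm = n_perm, alpha = alpha,
                               seed = seed)
  list(selective = any(res$global_sig),
       n_sig_positions = sum(res$global_sig),
       result = res)
}

#' Spatial information of a rate map (bits/spike)
#'
#' Occupancy-weighted per-spike information
#' `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)`
#' over occupied bins with positive rate, with `p_i` the occupancy
#' probability and `lambda_bar = sum p_i lambda_i`. Zero iff the rate is
#' constant over occupied bins; invariant under uniform rate rescaling.
#'
#' @param map A [rate_map()] (pooled condition is used).
#' @return List with `information` (bits/spike), `mean_rate`, `p` and
#'   `rate` per bin.
#' @export
spatial_information <- function(map) {
  occ <- map$occupancy[, "pooled"]
  lam <- map$rate[, "pooled"]
  keep <- occ > 0
  p <- occ[keep] / sum(occ[keep])
  lam <- lam[keep]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop("mean rate is zero: spatial information undefined")
  pos <- lam > 0
  info <- sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
  list(information = info, mean_rate = lbar, p = p, rate = lam)
}

#' Stage-wise population-average rate curves with early-vs-late comparison
#'
#' Averages unit rate curves within each learning stage (mean and SEM per
#' position) and compares early vs late positionwise with
#' [band_permutation_test()], treating units as exchangeable observations.
#'
#' @param curves Matrix, units x positions (e.g. pooled [rate_map()] rate
#'   rows).
#' @param stages Per-unit stage factor with levels including `early` and
#'   `late`.
#' @param n_perm,alpha,seed Passed to [band_permutation_test()].
#' @return List with `mean` and `sem` (stage x position matrices), and
#'   `early_vs_late` (a `band_perm_result`).
#' @export
population_stage_average <- function(curves, stages, n_perm = 1000,
                                     alpha = 0.05, seed = NULL) {
  curves <- as.matrix(curves)
  stages <- factor(stages)
  if (any(table(stages) < 2)) stop("need >= 2 units per stage")
  mu <- t(sapply(levels(stages), function(g)
    colMeans(curves[stages == g, , drop = FALSE])))
  se <- t(sapply(levels(stages), function(g) {
    X <- curves[stages == g, , drop = FALSE]
    apply(X, 2, sd) / sqrt(nrow(X))
  }))
  sel <- stages %in% c("early", "late")
  fam <- curve_family(curves[sel, , drop = FALSE], droplevels(stages[sel]))
  res <- band_permutation_test(fam, n_perm = n_perm, alpha = alpha,
                               seed = seed)
  list(mean = mu, sem = se, early_vs_late = res)
}
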