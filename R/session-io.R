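SCHEMA_VERSION <- "1.0"

#' Construct a recording-session container
#'
#' One recording day: per-trial events, head tracking, spike-sorted units
#' with mean waveforms, and per-region LFP traces, all on one session clock
#' (seconds from session start).
#'
#' @param meta List with at least `rat_id`, `session_index`, `fs_lfp`,
#'   `fs_track`, `zone_start`, `zone_length`.
#' @param trials Data frame: `trial`, `stimulus` (`Stim1`/`Stim2`),
#'   `choice` (`left`/`right`), `correct`, `t_entry`, `t_exit`, `t_choice`.
#' @param tracking Data frame: `t`, `x`, `y`.
#' @param units Named list; each element `list(region, spike_times,
#'   waveform, fs_wave)`.
#' @param lfp Named list per region of `list(samples, fs)` or a bare
#'   numeric vector (then `meta$fs_lfp` applies).
#' @return Object of class `maze_session`.
#' @export
session <- function(meta, trials, tracking, units = list(), lfp = list()) {
  lfp <- lapply(lfp, function(l) {
    if (is.numeric(l)) list(samples = l, fs = meta$fs_lfp) else l
  })
  meta$schema <- meta$schema %||% SCHEMA_VERSION
  s <- structure(list(meta = meta, trials = trials, tracking = tracking,
                      units = units, lfp = lfp),
                 class = "maze_session")
  validate_session(s)
  s
}

#' @export
print.maze_session <- function(x, ...) {
  cat(sprintf("maze_session: rat %s session %s | %d trials, %d units, LFP: %s\n",
              x$meta$rat_id, x$meta$session_index, nrow(x$trials),
              length(x$units), paste(names(x$lfp), collapse = ", ")))
  invisible(x)
}

#' Validate a session against the container schema
#'
#' Collects every failing field and reports them all in one error, so a
#' malformed file can be fixed in a single pass. Inconsistencies that are
#' tolerable (LFP length off the nominal duration by more than one sample)
#' raise warnings.
#'
#' @param s A [session()] object.
#' @return Invisibly `TRUE`; errors with the full list of failures.
#' @export
validate_session <- function(s) {
  bad <- character(0)
  req_meta <- c("rat_id", "session_index", "fs_lfp", "fs_track",
                "zone_start", "zone_length")
  miss <- setdiff(req_meta, names(s$meta))
  if (length(miss)) bad <- c(bad, paste0("/meta missing: ",
                                         paste(miss, collapse = ", ")))
  if (is.null(s$trials)) bad <- c(bad, "/trials missing")
  else {
    req_tr <- c("trial", "stimulus", "choice", "correct",
                "t_entry", "t_exit", "t_choice")
    miss <- setdiff(req_tr, names(s$trials))
    if (length(miss)) bad <- c(bad, paste0("/trials missing columns: ",
                                           paste(miss, collapse = ", ")))
    else {
      if (!all(s$trials$stimulus %in% c("Stim1", "Stim2")))
        bad <- c(bad, "/trials stimulus not in {Stim1, Stim2}")
      if (!all(s$trials$choice %in% c("left", "right")))
        bad <- c(bad, "/trials choice not in {left, right}")
      with(s$trials, {
        if (any(!(t_entry < t_exit & t_exit <= t_choice)))
          bad <<- c(bad, "/trials timestamps violate t_entry < t_exit <= t_choice")
      })
    }
  }
  if (is.null(s$tracking) || !all(c("t", "x", "y") %in% names(s$tracking)))
    bad <- c(bad, "/tracking missing or lacks t, x, y")
  else if (is.unsorted(s$tracking$t))
    bad <- c(bad, "/tracking timestamps not sorted")
  for (id in names(s$units)) {
    u <- s$units[[id]]
    miss <- setdiff(c("region", "spike_times", "waveform", "fs_wave"), names(u))
    if (length(miss))
      bad <- c(bad, paste0("/units/", id, " missing: ",
                           paste(miss, collapse = ", ")))
    else if (is.unsorted(u$spike_times, strictly = TRUE) &&
             length(u$spike_times) > 1)
      bad <- c(bad, paste0("/units/", id, " spike_times not strictly increasing"))
  }
  for (r in names(s$lfp)) {
    l <- s$lfp[[r]]
    if (!all(c("samples", "fs") %in% names(l)))
      bad <- c(bad, paste0("/lfp/", r, " missing samples or fs"))
  }
  if (length(bad)) stop("session schema violations:\n  ",
                        paste(bad, collapse = "\n  "))
  # soft check: LFP length vs session duration
  if (!is.null(s$tracking) && length(s$lfp)) {
    dur <- max(s$tracking$t)
    for (r in names(s$lfp)) {
      l <- s$lfp[[r]]
      if (abs(length(l$samples) - dur * l$fs) > max(1, 0.01 * l$fs * dur))
        warning("/lfp/", r, " length inconsistent with fs * duration")
    }
  }
  invisible(TRUE)
}

#' Write / read a session as a plain-text directory store
#'
#' The store mirrors the container's group structure: `meta.yaml`,
#' `trials.csv`, `tracking.csv`, `lfp_<region>.csv`, and per-unit
#' `units/<id>_spikes.csv` / `units/<id>_waveform.csv`. Numeric arrays are
#' written with 17 significant digits, so a write/read round trip
#' reproduces every double bit-exactly. A ground-truth object (from the
#' synthetic generator) is stored as a `ground_truth.yaml` sidecar.
#'
#' @param s A [session()] object.
#' @param path Directory to create/read.
#' @param truth Optional ground-truth list/data frame sidecar.
#' @return `write_session`: the path, invisibly. `read_session`: a
#'   validated `maze_session` (ground truth, when present, in attribute
#'   `"truth"`).
#' @export
write_session <- function(s, path, truth = attr(s, "truth")) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "units"), showWarnings = FALSE)
  meta <- s$meta
  meta$units <- lapply(s$units, function(u)
    list(region = u$region, fs_wave = u$fs_wave, class = u$class %||% NULL))
  meta$lfp <- lapply(s$lfp, function(l) list(fs = l$fs))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  write_num_csv(s$trials, file.path(path, "trials.csv"))
  write_num_csv(s$tracking, file.path(path, "tracking.csv"))
  for (r in names(s$lfp))
    write_num_csv(data.frame(v = s$lfp[[r]]$samples),
                  file.path(path, paste0("lfp_", r, ".csv")))
  for (id in names(s$units)) {
    u <- s$units[[id]]
    write_num_csv(data.frame(t = u$spike_times),
                  file.path(path, "units", paste0(id, "_spikes.csv")))
    write_num_csv(data.frame(v = u$waveform),
                  file.path(path, "units", paste0(id, "_waveform.csv")))
  }
  if (!is.null(truth))
    yaml::write_yaml(.truth_to_yaml(truth), file.path(path, "ground_truth.yaml"))
  invisible(path)
}

.truth_to_yaml <- function(truth) {
  rapply(truth, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, how = "replace", classes = "ANY")
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.yaml")
  if (!file.exists(mf)) stop("session store invalid: missing /meta (meta.yaml)")
  meta <- yaml::read_yaml(mf)
  tf <- file.path(path, "trials.csv")
  if (!file.exists(tf)) stop("session store invalid: missing /trials (trials.csv)")
  trials <- read_num_csv(tf, c("t_entry", "t_exit", "t_choice"))
  trials$correct <- as.logical(trials$correct)
  kf <- file.path(path, "tracking.csv")
  if (!file.exists(kf)) stop("session store invalid: missing /tracking (tracking.csv)")
  tracking <- read_num_csv(kf, c("t", "x", "y"))
  units <- list()
  for (id in names(meta$units)) {
    um <- meta$units[[id]]
    sp <- read_num_csv(file.path(path, "units", paste0(id, "_spikes.csv")), "t")
    wv <- read_num_csv(file.path(path, "units", paste0(id, "_waveform.csv")), "v")
    units[[id]] <- list(region = um$region, spike_times = sp$t,
                        waveform = wv$v, fs_wave = um$fs_wave,
                        class = um$class %||% NULL)
  }
  lfp <- list()
  for (r in names(meta$lfp)) {
    v <- read_num_csv(file.path(path, paste0("lfp_", r, ".csv")), "v")
    lfp[[r]] <- list(samples = v$v, fs = meta$lfp[[r]]$fs)
  }
  meta$units <- NULL; meta$lfp <- NULL
  s <- session(meta, trials, tracking, units, lfp)
  gt <- file.path(path, "ground_truth.yaml")
  if (file.exists(gt)) attr(s, "truth") <- yaml::read_yaml(gt)
  s
}

# normalized distance of x positions within the judgment zone
normalized_distance <- function(s, x) {
  (x - s$meta$zone_start) / s$meta$zone_length
}

#' Judgment-zone traversal epochs of a session
#'
#' @param s A [session()].
#' @return Two-column matrix of `[t_entry, t_exit)` intervals, one row per
#'   trial, for use as an epoch mask.
#' @export
zone_epochs <- function(s) {
  cbind(start = s$trials$t_entry, end = s$trials$t_exit)
}
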