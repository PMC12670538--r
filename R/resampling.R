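#' Curve family for two-condition comparison
#'
#' Bundles a trials x positions matrix of a real quantity (lateral position
#' in maze units, firing rate in Hz, ...) sampled on a common
#' normalized-distance grid, with a two-level per-trial condition label.
#'
#' @param curves Numeric matrix, one row per trial, one column per grid
#'   position. No missing values are allowed after preprocessing.
#' @param labels Per-trial condition tag with exactly two levels and at
#'   least two trials per level.
#' @param positions Optional numeric grid (defaults to bin centers
#'   `(i - 0.5)/ncol` on `[0, 1]`).
#' @return An object of class `curve_family`.
#' @export
curve_family <- function(curves, labels, positions = NULL) {
  curves <- as.matrix(curves)
  storage.mode(curves) <- "double"
  labels <- as.factor(as.vector(labels))
  if (nrow(curves) != length(labels))
    stop("one label per curve row is required")
  if (anyNA(curves)) stop("curves contain missing values; preprocess first")
  if (nlevels(labels) != 2L)
    stop("exactly two label levels are required, got ", nlevels(labels))
  if (any(table(labels) < 2L))
    stop("each level needs at least 2 trials")
  if (is.null(positions)) {
    p <- ncol(curves)
    positions <- (seq_len(p) - 0.5) / p
  }
  stopifnot(length(positions) == ncol(curves))
  structure(list(curves = curves, labels = labels,
                 positions = as.numeric(positions)),
            class = "curve_family")
}

# difference of level means for a set of A-index assignments.
# assign_A: list of integer vectors (rows assigned to level A).
# Returns matrix length(assign_A) x positions.
.diff_matrix <- function(curves, assign_A, nA, nB) {
  n <- nrow(curves)
  W <- matrix(-1 / nB, nrow = length(assign_A), ncol = n)
  for (i in seq_along(assign_A)) W[i, assign_A[[i]]] <- 1 / nA
  W %*% curves
}

#' Exhaustively enumerated permutation null for a curve family
#'
#' Enumerates every assignment of the level-A label to `nA` of the trials
#' exactly once (the observed assignment included) and returns the
#' difference-of-means curve for each. The Monte-Carlo engine converges to
#' the quantiles of this set as the number of permutations grows.
#'
#' @param family A [curve_family()].
#' @param max_assignments Safety cap on `choose(n, nA)` (default `1e6`).
#' @return Matrix of null differences, `choose(n, nA)` rows, one column per
#'   position. The observed assignment's row index is attached as attribute
#'   `"observed_row"`.
#' @export
exhaustive_null <- function(family, max_assignments = 1e6) {
  stopifnot(inherits(family, "curve_family"))
  lv <- levels(family$labels)
  idxA <- which(family$labels == lv[1L])
  n <- nrow(family$curves); nA <- length(idxA); nB <- n - nA
  n_assign <- choose(n, nA)
  if (n_assign > max_assignments)
    stop("choose(", n, ", ", nA, ") = ", n_assign,
         " assignments exceed the enumeration cap; use the Monte-Carlo engine")
  combos <- utils::combn(n, nA, simplify = FALSE)
  D <- .diff_matrix(family$curves, combos, nA, nB)
  obs_row <- which(vapply(combos, function(s) identical(s, sort(idxA)),
                          logical(1)))[1]
  attr(D, "observed_row") <- obs_row
  D
}

#' Permutation test with pointwise and globally corrected significance bands
#'
#' Tests, at every grid position, whether the mean curve of condition A
#' differs from condition B, by permuting condition labels over trials.
#' Pointwise bands are empirical order-statistic quantiles of the null
#' differences at level `alpha`; the global band widens them to the largest
#' achievable level `alpha' <= alpha` at which the fraction of null datasets
#' exceeding the band *anywhere* is at most `alpha`, which controls the
#' familywise error over positions. The achieved global level is reported
#' rather than pretending the nominal level is met exactly on the discrete
#' permutation grid.
#'
#' @param family A [curve_family()].
#' @param n_perm Number of random label permutations (default 5000). The
#'   observed labeling is always included in the null set, so Monte-Carlo
#'   p-values are of the form `(1 + b) / (1 + n_perm)`.
#' @param alpha Two-sided pointwise significance level (default 0.05).
#' @param seed Optional RNG seed for the permutation draw.
#' @param exhaustive If `TRUE`, enumerate all label assignments instead of
#'   sampling (`n_perm` is ignored).
#' @return Object of class `band_perm_result`: a list with `positions`,
#'   `observed_diff`, `pointwise_band` / `global_band` (2-row matrices,
#'   `low`/`high`), `pointwise_sig` / `global_sig` logical flags,
#'   `p_pointwise`, `n_null` (size of the null set, observed included),
#'   `alpha`, and `global_alpha_achieved`.
#' @details Ties between the observed difference and null differences are
#'   counted against significance (conservative). With zero variance
#'   everywhere the result is all-nonsignificant with a warning.
#' @export
band_permutation_test <- function(family, n_perm = 5000, alpha = 0.05,
                                  seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(family, "curve_family"), alpha > 0, alpha < 1)
  lv <- levels(family$labels)
  idxA <- sort(which(family$labels == lv[1L]))
  n <- nrow(family$curves); nA <- length(idxA); nB <- n - nA
  observed <- as.numeric(
    colMeans(family$curves[idxA, , drop = FALSE]) -
      colMeans(family$curves[-idxA, , drop = FALSE]))

  if (exhaustive) {
    D <- exhaustive_null(family)
    obs_row <- attr(D, "observed_row")
  } else {
    stopifnot(n_perm >= 1)
    assign_A <- with_seed(seed,
      lapply(seq_len(n_perm), function(i) sample.int(n, nA)))
    assign_A <- c(assign_A, list(idxA))  # identity assignment included
    D <- .diff_matrix(family$curves, assign_A, nA, nB)
    obs_row <- length(assign_A)
  }
  m <- nrow(D); P <- ncol(D)

  if (all(abs(D) < .Machine$double.eps * 100))
    warning("all null differences are zero; returning an all-nonsignificant result")

  # depth of each value within its column: min(#{<= v}, #{>= v});
  # ties counted on both sides (conservative)
  depth <- matrix(0L, m, P)
  for (j in seq_len(P)) {
    r_le <- rank(D[, j], ties.method = "max")
    r_ge <- m + 1L - rank(D[, j], ties.method = "min")
    depth[, j] <- pmin(r_le, r_ge)
  }
  depth_obs <- depth[obs_row, ]
  p_pointwise <- pmin(1, 2 * depth_obs / m)
  pointwise_sig <- p_pointwise <= alpha

  # order-statistic bands at rank k (k = 0 -> infinite band)
  band_at <- function(k) {
    if (k < 1) return(rbind(low = rep(-Inf, P), high = rep(Inf, P)))
    lo <- hi <- numeric(P)
    for (j in seq_len(P)) {
      s <- sort.int(D[, j], method = "quick")
      lo[j] <- s[k]; hi[j] <- s[m - k + 1L]
    }
    rbind(low = lo, high = hi)
  }
  k_pw <- floor(m * alpha / 2)
  pointwise_band <- band_at(k_pw)

  # familywise exceedance of band(k): dataset i exits somewhere iff its
  # minimal depth over positions is <= k (monotone in k)
  m_min <- apply(depth, 1L, min)
  exceed <- function(k) mean(m_min <= k)
  k_global <- 0L
  for (k in seq_len(max(k_pw, 0L))) {
    if (exceed(k) <= alpha) k_global <- k else break
  }
  global_band <- band_at(k_global)
  global_sig <- if (k_global >= 1L) depth_obs <= k_global else rep(FALSE, P)
  global_alpha_achieved <- if (k_global >= 1L) exceed(k_global) else 0

  structure(list(
    positions = family$positions,
    observed_diff = observed,
    levels = lv,
    pointwise_band = pointwise_band,
    global_band = global_band,
    pointwise_sig = pointwise_sig,
    global_sig = global_sig,
    p_pointwise = p_pointwise,
    n_null = m,
    alpha = alpha,
    k_pointwise = k_pw,
    k_global = k_global,
    global_alpha_achieved = global_alpha_achieved,
    exhaustive = isTRUE(exhaustive)
  ), class = "band_perm_result")
}

#' @export
print.band_perm_result <- function(x, ...) {
  cat("Permutation band test (", if (x$exhaustive) "exhaustive"
      else paste0(x$n_null - 1, " permutations"), ")\n", sep = "")
  cat(sprintf("  positions: %d, alpha = %g, achieved global level = %g\n",
              length(x$positions), x$alpha, x$global_alpha_achieved))
  cat(sprintf("  pointwise significant: %d, globally significant: %d\n",
              sum(x$pointwise_sig), sum(x$global_sig)))
  invisible(x)
}

#' @export
as.data.frame.band_perm_result <- function(x, ...) {
  data.frame(position = x$positions,
             observed_diff = x$observed_diff,
             pointwise_low = x$pointwise_band["low", ],
             pointwise_high = x$pointwise_band["high", ],
             global_low = x$global_band["low", ],
             global_high = x$global_band["high", ],
             p_pointwise = x$p_pointwise,
             pointwise_sig = x$pointwise_sig,
             global_sig = x$global_sig)
}

#' Earliest sustained divergence position of a band permutation result
#'
#' Returns the smallest grid position at which the curves are significantly
#' different and remain so for at least `k_run` contiguous bins; used to
#' locate the trajectory bifurcation (judgment point). `NA` if no such run.
#'
#' @param result A [band_permutation_test()] result.
#' @param k_run Minimum contiguous run length in bins (default 3).
#' @param which Significance mask to use, `"global"` (default) or
#'   `"pointwise"`.
#' @return Grid position (normalized distance) or `NA_real_`.
#' @export
first_divergence <- function(result, k_run = 3, which = c("global", "pointwise")) {
  stopifnot(inherits(result, "band_perm_result"), k_run >= 1)
  which <- match.arg(which)
  sig <- if (which == "global") result$global_sig else result$pointwise_sig
  if (!any(sig)) return(NA_real_)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= k_run
  if (!any(ok)) return(NA_real_)
  result$positions[starts[which(ok)[1L]]]
}
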