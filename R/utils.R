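#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb an enclosing
#' simulation stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gaussian-kernel smoothing of a regularly sampled series
#'
#' Discrete convolution with a normalized Gaussian kernel; the series is
#' reflected at both ends so a constant input is returned unchanged.
#' `sigma = 0` is the identity.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in samples.
#' @return Smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(is.numeric(x), sigma >= 0)
  if (sigma == 0 || length(x) < 3) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  # reflection padding
  pre <- x[pmin(n, pmax(1, seq(half + 1, 2)))]
  post <- x[pmin(n, pmax(1, seq(n - 1, n - half)))]
  xp <- c(pre, x, post)
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Real numeric vector.
#' @return Complex vector `x + i*H(x)`.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# degrees <-> radians
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) (r * 180 / pi) %% 360

# circular mean of angles in degrees, in [0, 360)
circ_mean_deg <- function(deg) {
  z <- sum(exp(1i * deg2rad(deg)))
  rad2deg(Arg(z))
}

# smallest absolute angular difference in degrees
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision numeric CSV writer/reader (17 significant digits survives
# a double -> text -> double round trip bit-exactly)
write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_num_csv <- function(path, numeric_cols) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(numeric_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  df
}
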