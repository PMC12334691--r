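#' @keywords internal
"_PACKAGE"

# Centered moving mean with shrunken windows at the edges, so no padding
# artifact enters the trace ends. window = 1 is the identity.
#' Moving-mean smoothing
#'
#' Centered moving average used throughout the trace-processing pipeline.
#' Edge samples are averaged over the shrunken window that fits inside the
#' trace, so the output has the same length and no padding bias.
#'
#' @param x Numeric vector, or a matrix smoothed row-wise.
#' @param window Window length in samples (default 4).
#' @return Smoothed object of the same shape as `x`.
#' @export
smooth_trace <- function(x, window = 4L) {
  if (is.matrix(x)) {
    return(t(apply(x, 1L, smooth_trace, window = window)))
  }
  stopifnot(is.numeric(x), window >= 1)
  n <- length(x)
  if (window > n) stop("smoothing window longer than trace")
  if (window == 1L) return(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# First-order exponential low-pass with exact step-invariant update,
# y[i] = y[i-1] + (x[i] - y[i-1]) * (1 - exp(-dt/tau)).
lowpass1 <- function(x, dt, tau, init = 0) {
  a <- 1 - exp(-dt / tau)
  y <- numeric(length(x))
  prev <- init
  for (i in seq_along(x)) {
    prev <- prev + (x[i] - prev) * a
    y[i] <- prev
  }
  y
}

relu <- function(x) pmax(x, 0)

# with_seed: run code under a local RNG state without disturbing the
# caller's stream; seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
}

#' Format a count as a percentage
#'
#' The reporting code path for all printed proportions: `100 * k / n`
#' rounded to `digits` decimals (e.g. 43 of 64 prints as 67.2).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage.
#' @export
format_proportion <- function(k, n, digits = 1L) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n, digits)
}

#' Format a ratio of two response amplitudes as a percentage
#'
#' @param a Numerator amplitude (e.g. ipsilateral peak dF/F).
#' @param b Denominator amplitude (e.g. maximal contralateral dF/F).
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage `100 * a / b`, rounded.
#' @export
format_ratio <- function(a, b, digits = 1L) {
  stopifnot(b != 0)
  round(100 * a / b, digits)
}
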