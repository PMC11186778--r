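# Shared low-level numeric helpers: 1-d smoothing kernels and moving averages
# used by both the fluorescence and the kinematics preprocessing.

#' Gaussian smoothing of a numeric series
#'
#' Convolves `x` with a discrete Gaussian kernel (truncated at `radius`
#' standard deviations on each side, renormalised to sum to one). Edges are
#' handled by reflecting the series, so constant inputs are returned
#' unchanged.
#'
#' @param x numeric vector.
#' @param sd kernel standard deviation in samples.
#' @param radius kernel half-width in samples; defaults to `ceiling(4 * sd)`.
#' @return numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sd, radius = ceiling(4 * sd)) {
  stopifnot(is.numeric(x), sd > 0)
  n <- length(x)
  if (n <= radius) {
    abort("trace shorter than the smoothing kernel half-width")
  }
  k <- dnorm(seq(-radius, radius), sd = sd)
  k <- k / sum(k)
  pad <- c(rev(x[seq_len(radius) + 1L]), x, rev(x[n - seq_len(radius)]))
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(radius + 1L):(radius + n)])
}

#' Running-median smoothing
#'
#' Thin wrapper around [stats::runmed()] with median end rule, used as the
#' spike-rejection stage of the fluorescence and velocity filters.
#'
#' @param x numeric vector.
#' @param width odd window width in samples.
#' @return numeric vector, same length as `x`.
#' @export
median_smooth <- function(x, width) {
  stopifnot(width %% 2 == 1)
  if (length(x) < width) abort("trace shorter than the median filter width")
  as.numeric(runmed(x, width, endrule = "median"))
}

# Centred moving average whose window shrinks at the edges, so the output has
# the same length as the input and constant series are preserved.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 1L) return(x)
  half_lo <- floor((width - 1) / 2)
  half_hi <- ceiling((width - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# seconds -> samples, rounded to the nearest sample (never below `min`).
seconds_to_samples <- function(s, sample_rate, min = 1L) {
  pmax(as.integer(round(s * sample_rate)), min)
}

first_upper <- function(x) toupper(trimws(as.character(x)))
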