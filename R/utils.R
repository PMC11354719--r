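# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nearest odd integer >= 3 (Savitzky-Golay windows must be odd).
odd_at_least <- function(n, lo = 5L) {
  n <- max(as.integer(lo), as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

#' Mean of the lowest decile of a vector
#'
#' Averages the 10% lowest values of `x` (at least one value). This is the
#' rule used to turn a transit trace into a single voltage level.
#'
#' @param x Numeric vector with at least 10 elements.
#' @return Scalar mean of the `floor(length(x)/10)` smallest values.
#' @export
lowest_decile_mean <- function(x) {
  if (length(x) < 10L) {
    stop("lowest_decile_mean() needs a window of at least 10 samples")
  }
  k <- max(1L, floor(length(x) / 10))
  mean(sort(x, partial = k)[seq_len(k)])
}

# Savitzky-Golay smoothing with cached filter matrices: designing the
# filter (an SVD of the local polynomial basis) costs far more than
# applying it, and the same few window lengths recur for every event.
sg_cache <- new.env(parent = emptyenv())

sg_smooth <- function(x, p, n) {
  key <- paste0(p, "_", n)
  f <- sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = p, n = n)
    sg_cache[[key]] <- f
  }
  signal::sgolayfilt(x, f)
}

# Robust per-sample noise SD: MAD of first differences over sqrt(2).
# Transit dips contribute only a handful of large differences, which the
# median absolute deviation ignores.
robust_noise_sd <- function(x) {
  if (length(x) < 3L) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

# Hann-windowed magnitude spectrum, zero-padded for frequency interpolation.
# Returns list(freq, mag) for the non-negative frequencies.
magnitude_spectrum <- function(x, sampling_rate, zero_pad = 8L) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 2^ceiling(log2(max(n * zero_pad, 64)))
  mag <- Mod(stats::fft(c(x * w, rep(0, nfft - n))))
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1L) * sampling_rate / nfft, mag = mag[half])
}

# Running-median spectral floor; width in bins (forced odd).
spectral_floor <- function(mag, width) {
  width <- odd_at_least(width, 5L)
  if (length(mag) <= width) return(rep(stats::median(mag), length(mag)))
  stats::runmed(mag, width, endrule = "median")
}

# Parabolic interpolation of a spectral peak at index i; returns fractional
# bin offset in [-0.5, 0.5].
parabolic_offset <- function(mag, i) {
  if (i <= 1L || i >= length(mag)) return(0)
  denom <- mag[i - 1L] - 2 * mag[i] + mag[i + 1L]
  if (denom == 0) return(0)
  d <- 0.5 * (mag[i - 1L] - mag[i + 1L]) / denom
  max(-0.5, min(0.5, d))
}

# Derive a 32-bit safe child seed from a base seed and a stream index.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
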