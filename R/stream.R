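#' Raw sensor voltage stream
#'
#' Container for a sampled voltage segment from the receiver photodetector.
#' `baseline_v0` records the nominal no-target background voltage when it is
#' known (e.g. for simulated streams); detection can alternatively estimate
#' a drifting baseline with [estimate_baseline()].
#'
#' @param samples Numeric vector of voltages; must be finite.
#' @param sampling_rate Sampling rate in Hz (default 30517).
#' @param start_time Timestamp of the first sample (`POSIXct`, UTC).
#' @param baseline_v0 Optional known background voltage, volts.
#' @return An object of class `raw_stream`.
#' @export
raw_stream <- function(samples, sampling_rate = 30517,
                       start_time = as.POSIXct("2022-01-01", tz = "UTC"),
                       baseline_v0 = NULL) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop("'samples' must be a finite numeric vector")
  }
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.null(baseline_v0)) stopifnot_scalar(baseline_v0, "baseline_v0")
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         start_time = start_time, baseline_v0 = baseline_v0),
    class = "raw_stream"
  )
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("Raw sensor stream: %d samples @ %.0f Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.null(x$baseline_v0)) {
    cat(sprintf("  nominal baseline V0 = %.4g V\n", x$baseline_v0))
  }
  cat(sprintf("  start: %s\n", format(x$start_time, usetz = TRUE)))
  invisible(x)
}

#' @export
length.raw_stream <- function(x) length(x$samples)
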