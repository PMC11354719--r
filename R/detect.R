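#' Detection configuration
#'
#' Tuning parameters of transit-event detection and insect discrimination.
#' The detection threshold is adaptive, `k` robust noise standard deviations
#' below the baseline, with an absolute floor for essentially noise-free
#' streams. Candidate events shorter than `min_duration` (default 10 ms) are
#' disregarded as too short to record enough wing cycles; events longer than
#' `max_duration` (default 1 s, the approximate maximum a transit can reach)
#' are retained but labeled non-insect. Wing content is looked for in
#' `insect_band` (default 10-900 Hz).
#'
#' @param threshold_k Threshold in robust noise SDs below baseline.
#' @param threshold_floor_v Absolute minimum threshold, volts.
#' @param min_duration,max_duration Event duration bounds, seconds.
#' @param insect_band Two-element Hz interval searched for wingbeat content.
#' @param band_power_ratio_min Minimum ratio of a spectral peak to the local
#'   spectral floor for an event to be called an insect.
#' @param bridge_gap Sub-threshold gaps shorter than this (seconds) inside
#'   one transit are bridged so wing oscillations touching baseline do not
#'   split an event.
#' @param baseline_window Rolling-baseline window in seconds (default
#'   `10 * max_duration`, so the estimate is immune to single transits).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_k = 6, threshold_floor_v = 0.001,
                             min_duration = 0.010, max_duration = 1.0,
                             insect_band = c(10, 900),
                             band_power_ratio_min = 5,
                             bridge_gap = 0.002,
                             baseline_window = NULL) {
  if (!(min_duration > 0 && min_duration < max_duration)) {
    stop("need 0 < min_duration < max_duration")
  }
  if (length(insect_band) != 2L || any(insect_band <= 0) ||
      insect_band[1] >= insect_band[2]) {
    stop("'insect_band' must be a positive increasing Hz interval")
  }
  structure(
    list(threshold_k = threshold_k, threshold_floor_v = threshold_floor_v,
         min_duration = min_duration, max_duration = max_duration,
         insect_band = insect_band,
         band_power_ratio_min = band_power_ratio_min,
         bridge_gap = bridge_gap,
         baseline_window = baseline_window %||% (10 * max_duration)),
    class = "detection_config"
  )
}

#' Estimate a slowly drifting baseline
#'
#' Per-sample estimate of the no-target background voltage V0(t): medians of
#' short chunks are smoothed with a rolling median spanning `window` seconds
#' and interpolated back to the sample grid. Because the rolling window is
#' an order of magnitude longer than the longest transit, the estimate
#' tracks slow drift (temperature, alignment) while ignoring transits.
#'
#' @param stream A [raw_stream()].
#' @param window Rolling window in seconds (default 10).
#' @param chunk Chunk length in seconds for the first-stage medians.
#' @return Numeric vector of per-sample baseline estimates.
#' @export
estimate_baseline <- function(stream, window = 10, chunk = window / 40) {
  v <- stream$samples
  fs <- stream$sampling_rate
  if (length(v) / fs < window) {
    stop("segment shorter than the baseline window; pass a known baseline")
  }
  csize <- max(2L, round(chunk * fs))
  nchunk <- floor(length(v) / csize)
  idx <- rep(seq_len(nchunk), each = csize)
  med <- unname(tapply(v[seq_len(nchunk * csize)], idx, stats::median))
  k <- odd_at_least(window / chunk, 3L)
  if (nchunk > k) med <- stats::runmed(med, k, endrule = "median")
  centers <- (seq_len(nchunk) - 0.5) * csize
  stats::approx(centers, med, xout = seq_along(v), rule = 2)$y
}

# Resolve the baseline for detection: explicit > estimated > nominal.
resolve_baseline <- function(stream, config, baseline) {
  if (!is.null(baseline)) {
    if (length(baseline) == 1L) return(rep(baseline, length(stream$samples)))
    if (length(baseline) != length(stream$samples)) {
      stop("'baseline' must be a scalar or one value per sample")
    }
    return(baseline)
  }
  if (length(stream$samples) / stream$sampling_rate >=
      config$baseline_window) {
    return(estimate_baseline(stream, window = config$baseline_window))
  }
  if (!is.null(stream$baseline_v0)) {
    return(rep(stream$baseline_v0, length(stream$samples)))
  }
  stop("stream too short to estimate a baseline and no baseline_v0 known")
}

# Runs of TRUE in a logical vector as a 2-column matrix [start, end) .
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values] + 1L)
}

# Merge [start, end) rows whose gap to the previous row is < gap samples.
merge_runs <- function(runs, gap = 0L) {
  if (nrow(runs) < 2L) return(runs)
  newgrp <- c(TRUE, runs[-1L, "start"] - runs[-nrow(runs), "end"] >= gap)
  grp <- cumsum(newgrp)
  cbind(start = as.integer(tapply(runs[, "start"], grp, min)),
        end = as.integer(tapply(runs[, "end"], grp, max)))
}

# Candidate transit runs before duration filtering: sub-threshold runs,
# gap-bridged, each expanded outward to the noise ceiling where the dip
# emerges from / returns to baseline. Shared by event detection and
# rain-saturation flagging.
candidate_runs <- function(stream, config, baseline = NULL) {
  v <- stream$samples
  fs <- stream$sampling_rate
  b <- resolve_baseline(stream, config, baseline)
  sd_n <- robust_noise_sd(v)
  threshold <- max(config$threshold_k * sd_n, config$threshold_floor_v)
  core <- logical_runs(v < b - threshold)
  if (nrow(core) == 0L) {
    return(cbind(start = integer(), end = integer()))
  }
  core <- merge_runs(core, round(config$bridge_gap * fs))
  ceiling_v <- max(3.5 * sd_n, 1e-9)
  wide <- logical_runs(v < b - ceiling_v)
  wi_s <- findInterval(core[, "start"], wide[, "start"])
  wi_e <- findInterval(core[, "end"] - 1L, wide[, "start"])
  refined <- cbind(start = wide[wi_s, "start"], end = wide[wi_e, "end"])
  refined <- refined[!duplicated(refined, MARGIN = 1), , drop = FALSE]
  merge_runs(refined)
}

#' Detect candidate transit events in a stream
#'
#' Finds contiguous runs where the signal drops below
#' `baseline - threshold`, bridges sub-threshold gaps shorter than the
#' configured bridge gap, and then expands each run outward to where the dip
#' sinks into the noise, so event bounds and transit times reflect the full
#' transit rather than the threshold crossing. Events shorter than
#' `min_duration` are disregarded; events longer than `max_duration` are
#' labeled `non_insect`; everything else is a `candidate`. Simultaneous
#' overlapping transits necessarily merge into a single recorded event.
#'
#' @param stream A [raw_stream()].
#' @param config A [detection_config()].
#' @param baseline Optional known baseline (scalar or per-sample). When
#'   missing, the baseline is estimated for long streams or taken from the
#'   stream's `baseline_v0`.
#' @return A data frame with one row per retained event: `event_id`,
#'   half-open sample indices `start`/`end`, `start_s`, `duration_s`,
#'   `label`.
#' @export
detect_events <- function(stream, config = detection_config(),
                          baseline = NULL) {
  fs <- stream$sampling_rate
  empty <- data.frame(event_id = integer(), start = integer(),
                      end = integer(), start_s = numeric(),
                      duration_s = numeric(), label = character())
  if (length(stream$samples) == 0L) return(empty)
  refined <- candidate_runs(stream, config, baseline)
  dur <- (refined[, "end"] - refined[, "start"]) / fs
  sel <- dur >= config$min_duration
  refined <- refined[sel, , drop = FALSE]
  dur <- dur[sel]
  if (nrow(refined) == 0L) return(empty)
  data.frame(
    event_id = seq_len(nrow(refined)),
    start = as.integer(refined[, "start"]),
    end = as.integer(refined[, "end"]),
    start_s = (refined[, "start"] - 1L) / fs,
    duration_s = dur,
    label = ifelse(dur > config$max_duration, "non_insect", "candidate")
  )
}

#' Insect vs non-insect discrimination of one event window
#'
#' An event is called an insect when its magnitude spectrum contains a
#' narrow peak inside the insect band whose height exceeds
#' `band_power_ratio_min` times the local spectral floor (a running median
#' across the band). Smooth dips -- water droplets, falling debris -- have
#' smoothly decaying spectra with no narrow line and fail the test.
#'
#' @param window Numeric voltage window of the event.
#' @param sampling_rate Sampling rate in Hz.
#' @param config A [detection_config()].
#' @return `"insect"` or `"non_insect"`.
#' @export
discriminate_insect <- function(window, sampling_rate,
                                config = detection_config()) {
  if (length(window) < 16L || stats::sd(window) == 0) return("non_insect")
  sp <- magnitude_spectrum(window, sampling_rate, zero_pad = 4L)
  band <- sp$freq >= config$insect_band[1] & sp$freq <= config$insect_band[2]
  if (!any(band)) return("non_insect")
  mag <- sp$mag[band]
  floor_w <- odd_at_least(sum(band) / 5, 51L)
  fl <- spectral_floor(mag, floor_w)
  ratio <- max(mag / pmax(fl, 1e-6 * max(sp$mag)))
  if (ratio > config$band_power_ratio_min) "insect" else "non_insect"
}

#' Label candidate events as insect or non-insect
#'
#' Applies [discriminate_insect()] to every `candidate` row of a detection
#' table; rows already labeled (e.g. overlong events) are left untouched.
#'
#' @param stream The [raw_stream()] the events were detected in.
#' @param events Data frame from [detect_events()].
#' @param config A [detection_config()].
#' @return The events data frame with updated `label`.
#' @export
label_events <- function(stream, events, config = detection_config()) {
  for (i in which(events$label == "candidate")) {
    w <- stream$samples[events$start[i]:(events$end[i] - 1L)]
    events$label[i] <- discriminate_insect(w, stream$sampling_rate, config)
  }
  events
}

#' Flag intervals where detection is impossible
#'
#' During heavy rain a continuous stream of droplets keeps the signal
#' sub-baseline and insect transits cannot be identified. Intervals where
#' the fraction of time covered by candidate transit runs exceeds
#' `saturation` are marked invalid; invalid time is excluded from the
#' measurement duration when computing aerial density rather than being
#' counted as zero. Sparse (light-rain) droplets leave their interval valid
#' and are instead rejected individually by the spectral insect test.
#'
#' Occupancy is measured against each interval's own upper signal envelope
#' (its 98th voltage percentile) rather than the rolling baseline: a
#' continuous droplet stream depresses median-based baseline estimates, but
#' the fraction of time the signal sits a full threshold below its upper
#' envelope still approaches one, which is precisely the condition under
#' which no individual transit can be isolated.
#'
#' @param stream A [raw_stream()].
#' @param config A [detection_config()].
#' @param resolution Interval length in seconds (default 60, the native
#'   density resolution).
#' @param saturation Maximum tolerated sub-envelope occupancy fraction.
#' @return Data frame with `interval_start_s`, `occupancy`, `valid`.
#' @export
flag_invalid_intervals <- function(stream, config = detection_config(),
                                   resolution = 60, saturation = 0.5) {
  v <- stream$samples
  fs <- stream$sampling_rate
  sd_n <- robust_noise_sd(v)
  threshold <- max(config$threshold_k * sd_n, config$threshold_floor_v)
  size <- max(1L, round(resolution * fs))
  nint <- ceiling(length(v) / size)
  idx <- rep(seq_len(nint), each = size, length.out = length(v))
  occ <- as.numeric(tapply(v, idx, function(w) {
    mean(w < stats::quantile(w, 0.98) - threshold)
  }))
  data.frame(
    interval_start_s = (seq_len(nint) - 1L) * resolution,
    occupancy = occ,
    valid = occ <= saturation
  )
}
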