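#' Wingbeat frequency of a transit signal
#'
#' Retrieves the fundamental wingbeat frequency by FFT: the window is
#' detrended with a Savitzky-Golay smooth to suppress the slow body dip,
#' Hann-windowed, zero-padded (>= 8x) and transformed; spectral peaks above
#' the local floor are located and the fundamental is the lowest substantial
#' peak whose harmonic pattern is consistent (support at twice the
#' frequency, or no peak at half of it -- guarding against returning the
#' first harmonic when it dominates). The peak position is refined by
#' parabolic interpolation, giving sub-bin resolution.
#'
#' Frequencies below three cycles per window cannot be resolved and yield
#' `NA`, as does a window without any in-band peak above the noise floor.
#'
#' @param window Numeric voltage window of the event.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Search band in Hz (default 10-900).
#' @param ratio_min Minimum peak-to-floor ratio for a usable peak.
#' @return Fundamental frequency in Hz, or `NA_real_` if undefined.
#' @examples
#' p <- transit_params(duration = 0.1, wingbeat_freq = 500,
#'                     body_depth = 0.006, wing_depth = 0.002)
#' v <- simulate_transit(p, 30517, 3)
#' wingbeat_frequency(v, 30517)
#' @export
wingbeat_frequency <- function(window, sampling_rate, band = c(10, 900),
                               ratio_min = 5) {
  n <- length(window)
  if (n < 32L || stats::sd(window) == 0) return(NA_real_)
  t_len <- n / sampling_rate
  nsg <- odd_at_least(32 * round(min(0.025 * sampling_rate, n / 3) / 32), 5L)
  if (nsg >= n) nsg <- odd_at_least(n / 3, 5L)
  detr <- window - sg_smooth(window, 3, nsg)
  sp <- magnitude_spectrum(detr, sampling_rate, zero_pad = 8L)
  f_lo <- max(band[1], 3 / t_len)
  sel <- which(sp$freq >= f_lo & sp$freq <= band[2])
  if (!length(sel)) return(NA_real_)
  mag <- sp$mag[sel]
  fl <- spectral_floor(mag, odd_at_least(length(sel) / 5, 51L))
  hot <- mag > ratio_min * pmax(fl, 1e-6 * max(sp$mag))
  if (!any(hot)) return(NA_real_)
  lobes <- logical_runs(hot)
  peaks <- t(apply(lobes, 1L, function(r) {
    i <- unname(r[1]) + which.max(mag[r[1]:(r[2] - 1L)]) - 1L
    c(i = i, mag = mag[i])
  }))
  df <- sp$freq[2] - sp$freq[1]
  freqs <- vapply(peaks[, "i"], function(i) {
    sp$freq[sel[1]] + (i - 1 + parabolic_offset(mag, as.integer(i))) * df
  }, numeric(1))
  keep <- peaks[, "mag"] >= 0.05 * max(peaks[, "mag"])
  freqs_k <- freqs[keep]
  ord <- order(freqs_k)
  freqs_k <- freqs_k[ord]
  # Magnitude of the strongest refined line within +/- 5% of frequency f0,
  # relative to the local floor; used for the subharmonic rescue below.
  line_at <- function(f0) {
    rng <- which(sp$freq[sel] >= 0.95 * f0 & sp$freq[sel] <= 1.05 * f0)
    if (!length(rng)) return(list(ok = FALSE))
    i <- rng[which.max(mag[rng])]
    list(ok = mag[i] > 3 * pmax(fl[i], 1e-6 * max(sp$mag)),
         freq = sp$freq[sel[1]] + (i - 1 + parabolic_offset(mag, i)) * df,
         mag = mag[i])
  }
  for (f in freqs_k) {
    sub <- any(freqs_k >= 0.4 * f & freqs_k <= 0.6 * f)
    sup <- any(freqs_k >= 1.8 * f & freqs_k <= 2.2 * f)
    if (!sub || sup) {
      # The slow body dip elevates the spectral floor at low frequencies and
      # can mask a true fundamental there. If half the selected frequency
      # still shows a line, and so does its third harmonic (which a genuine
      # fundamental at f/2 must have while a spurious low line does not),
      # step down to the subharmonic.
      if (!sub && f / 2 * t_len >= 3 && f / 2 >= f_lo) {
        half <- line_at(f / 2)
        third <- if (isTRUE(half$ok)) line_at(3 * half$freq) else list(ok = FALSE)
        if (isTRUE(half$ok) && isTRUE(third$ok)) return(half$freq)
      }
      if (f * t_len < 3) return(NA_real_)
      return(f)
    }
  }
  NA_real_
}

# Quadratic refinement of an extremum of `v` near index i using the raw
# samples within +/- h: averages sample noise instead of inheriting the
# bias of a single noisy extremum.
refine_extremum <- function(v, i, h, minimum = TRUE) {
  j <- max(1L, i - h):min(length(v), i + h)
  if (length(j) < 5L) return(c(x = i, y = v[i]))
  x <- j - i
  fit <- stats::lm.fit(cbind(1, x, x * x), v[j])
  co <- fit$coefficients
  ok <- if (minimum) co[3] > 0 else co[3] < 0
  if (!is.finite(co[3]) || !ok) return(c(x = i, y = v[i]))
  xv <- max(-h, min(h, -co[2] / (2 * co[3])))
  c(x = i + xv, y = co[1] + co[2] * xv + co[3] * xv^2)
}

# Extrema of the lightly smoothed window, refined on the raw samples.
envelope_nodes <- function(window, smoothed, spacing, h, minimum) {
  sig <- if (minimum) -smoothed else smoothed
  pk <- pracma::findpeaks(sig, minpeakdistance = max(1L, spacing))
  if (is.null(pk)) return(NULL)
  idx <- sort(pk[, 2])
  nodes <- t(vapply(idx, function(i) refine_extremum(window, i, h, minimum),
                    numeric(2)))
  n <- length(window)
  ends <- rbind(c(1, window[1]), c(n, window[n]))
  colnames(ends) <- colnames(nodes) <- c("x", "y")
  nodes <- rbind(ends[1, , drop = FALSE], nodes, ends[2, , drop = FALSE])
  nodes <- nodes[order(nodes[, "x"]), , drop = FALSE]
  nodes[!duplicated(round(nodes[, "x"])), , drop = FALSE]
}

#' Separate the wing and body contributions of a transit
#'
#' The body envelope is the transit level between wingbeats: the local
#' voltage maxima of the oscillating signal (smallest extinction, wings
#' folded) are located with a minimum spacing of 0.8 wingbeat periods,
#' refined by a local quadratic fit, and joined by shape-preserving cubic
#' (pchip) interpolation. The wing component is the remainder
#' `body - signal`, so the decomposition reconstructs the window exactly.
#' A second envelope through the per-beat voltage minima (wings extended)
#' gives the peak wing extinction trace used for the wing level Vw.
#'
#' Windows with fewer than three resolvable wingbeat cycles are flagged
#' `degenerate`; they get `body = signal` and a zero wing component.
#'
#' @param window Numeric voltage window of the event.
#' @param sampling_rate Sampling rate in Hz.
#' @param fw Optional known wingbeat frequency; estimated when missing.
#' @param band,ratio_min Passed to [wingbeat_frequency()] when estimating.
#' @return List with `body` (volts), `wing` (volts of extinction),
#'   `wing_peak` (per-beat peak wing extinction, volts), `fw`, `degenerate`.
#' @export
separate_wing_body <- function(window, sampling_rate, fw = NULL,
                               band = c(10, 900), ratio_min = 5) {
  n <- length(window)
  degenerate <- function() {
    list(body = window, wing = rep(0, n), wing_peak = rep(0, n),
         fw = fw %||% NA_real_, degenerate = TRUE)
  }
  if (is.null(fw)) {
    fw <- wingbeat_frequency(window, sampling_rate, band, ratio_min)
  }
  if (!is.finite(fw) || fw <= 0 || fw * n / sampling_rate < 3) {
    return(degenerate())
  }
  period <- sampling_rate / fw
  nsg <- odd_at_least(4 * round(period / 24), 5L)
  if (nsg >= n) return(degenerate())
  vs <- sg_smooth(window, 3, nsg)
  spacing <- max(2L, round(0.8 * period))
  h <- max(2L, round(period / 12))
  up <- envelope_nodes(window, vs, spacing, h, minimum = FALSE)
  lo <- envelope_nodes(window, vs, spacing, h, minimum = TRUE)
  if (is.null(up) || is.null(lo) || nrow(up) < 5L || nrow(lo) < 5L) {
    return(degenerate())
  }
  xs <- seq_len(n)
  body <- signal::pchip(up[, "x"], up[, "y"], xs)
  lower <- signal::pchip(lo[, "x"], lo[, "y"], xs)
  list(body = body, wing = body - window,
       wing_peak = pmax(body - lower, 0), fw = fw, degenerate = FALSE)
}

#' Transit voltage levels for wings and body
#'
#' Collapses the separated traces into the two voltage levels entering the
#' cross-section retrieval, each evaluated as the average of the 10% lowest
#' values: `VB` from the body trace, and `Vw` from the wing-contribution
#' trace referenced to the background voltage (i.e. `V0` minus the per-beat
#' peak wing extinction). A wingless event therefore has `Vw = V0`.
#'
#' @param decomposition Result of [separate_wing_body()].
#' @param v0 Background voltage V0 in volts.
#' @return List with elements `Vw` and `VB` (volts).
#' @export
transit_levels <- function(decomposition, v0) {
  stopifnot_scalar(v0, "v0")
  list(Vw = lowest_decile_mean(v0 - decomposition$wing_peak),
       VB = lowest_decile_mean(decomposition$body))
}

#' Optical extinction cross-sections of wings and body
#'
#' Converts the transit voltage levels into extinction cross-sections using
#' the beam cross-section area `A`:
#' `sigma_w = (V0 - Vw) / V0 * A` and `sigma_B = (V0 - VB) / V0 * A`.
#' Levels above `V0` (possible under noise) clamp the cross-section to zero
#' with a warning.
#'
#' @param v_w,v_b Wing and body voltage levels, volts.
#' @param v0 Background voltage, volts (> 0).
#' @param geometry A [beam_geometry()].
#' @return Named vector `c(sigma_w = , sigma_b = )` in m^2.
#' @examples
#' g <- beam_geometry(path_length = 1)
#' extinction_cross_sections(2.4, 2.7, 3.0, g)
#' @export
extinction_cross_sections <- function(v_w, v_b, v0,
                                      geometry = beam_geometry()) {
  if (!is.numeric(v0) || v0 <= 0) stop("'v0' must be positive")
  s <- c(sigma_w = (v0 - v_w) / v0, sigma_b = (v0 - v_b) / v0) *
    geometry$area
  if (any(s < 0)) {
    warning("voltage level above V0; clamping cross-section to 0")
    s <- pmax(s, 0)
  }
  s
}

#' Wing-to-body cross-section ratio
#'
#' `sigma_w / (sigma_w + sigma_b)`: close to 0 for insects whose optical
#' signature is dominated by the body (mosquitoes), approaching 1 for
#' broad-winged taxa. Undefined (NA, with a warning) when both
#' cross-sections are zero.
#'
#' @param sigma_w,sigma_b Wing and body extinction cross-sections, m^2.
#' @return Ratio in `[0, 1]` (vectorised), `NA` where undefined.
#' @export
wing_body_ratio <- function(sigma_w, sigma_b) {
  if (any(sigma_w < 0 | sigma_b < 0, na.rm = TRUE)) {
    stop("cross-sections must be non-negative")
  }
  tot <- sigma_w + sigma_b
  out <- ifelse(tot > 0, sigma_w / tot, NA_real_)
  if (anyNA(out)) warning("zero total cross-section; ratio undefined")
  out
}

#' Extract event features from a detected stream
#'
#' Runs the full per-event feature chain -- wingbeat frequency, wing/body
#' separation, 10%-lowest voltage levels, extinction cross-sections and
#' wing-to-body ratio -- for every event labeled `insect`.
#'
#' @param stream A [raw_stream()].
#' @param events Labeled event table from [label_events()].
#' @param config A [detection_config()].
#' @param geometry A [beam_geometry()].
#' @param baseline Optional known baseline (scalar or per-sample).
#' @return Data frame with one row per insect event: `event_id`, `start_s`,
#'   `duration_s`, `fw_hz`, `v_w`, `v_b`, `sigma_w_m2`, `sigma_b_m2`,
#'   `ratio_wb`, `degenerate`.
#' @export
extract_features <- function(stream, events, config = detection_config(),
                             geometry = beam_geometry(), baseline = NULL) {
  b <- resolve_baseline(stream, config, baseline)
  rows <- which(events$label == "insect")
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    idx <- events$start[i]:(events$end[i] - 1L)
    w <- stream$samples[idx]
    v0 <- mean(b[idx])
    dec <- separate_wing_body(w, stream$sampling_rate,
                              band = config$insect_band,
                              ratio_min = config$band_power_ratio_min)
    lev <- transit_levels(dec, v0)
    sig <- suppressWarnings(
      extinction_cross_sections(lev$Vw, lev$VB, v0, geometry))
    out[[k]] <- data.frame(
      event_id = events$event_id[i],
      start_s = events$start_s[i],
      duration_s = events$duration_s[i],
      fw_hz = dec$fw,
      v_w = lev$Vw, v_b = lev$VB,
      sigma_w_m2 = sig[["sigma_w"]], sigma_b_m2 = sig[["sigma_b"]],
      ratio_wb = if (sig[["sigma_w"]] + sig[["sigma_b"]] > 0) {
        sig[["sigma_w"]] / (sig[["sigma_w"]] + sig[["sigma_b"]])
      } else NA_real_,
      degenerate = dec$degenerate
    )
  }
  if (!length(out)) {
    return(data.frame(event_id = integer(), start_s = numeric(),
                      duration_s = numeric(), fw_hz = numeric(),
                      v_w = numeric(), v_b = numeric(),
                      sigma_w_m2 = numeric(), sigma_b_m2 = numeric(),
                      ratio_wb = numeric(), degenerate = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
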