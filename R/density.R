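#' Aerial density time series from transit events
#'
#' Converts timed transit events into absolute aerial density per time bin:
#' `rho_a = sum(dt_i) / (T_eff * V)`, where the sum runs over the transit
#' times of the in-bin events, `V` is the probe volume and
#' `T_eff = T * valid_fraction` is the valid observation time of the bin.
#' Because the estimate is a beam-occupancy integral rather than a count,
#' it is unbiased with respect to insect flight speed: fast fliers produce
#' many short transits, slow fliers few long ones, with equal total
#' occupancy at equal true density. Events spanning a bin edge contribute
#' their overlap duration to each bin. Bins with no valid time have
#' undefined (NA) density, not zero.
#'
#' @param events Data frame with columns `start_s` and `duration_s`
#'   (typically the insect-labeled rows of a detection table, or ledger
#'   rows).
#' @param t_start,t_end Time span covered by the series, seconds.
#' @param resolution Bin width T in seconds (default 60, the native
#'   resolution; coarser series are derived with [resample_density()]).
#' @param volume Probe volume V in m^3.
#' @param valid Optional per-bin validity: a logical/numeric vector of valid
#'   fractions (length = number of bins) or the data frame returned by
#'   [flag_invalid_intervals()] at the same resolution.
#' @return A data frame of class `density_series` with columns
#'   `bin_start_s`, `occupancy_s`, `valid_fraction`, `density_per_m3`, and
#'   attributes `resolution_s` and `volume`.
#' @export
aerial_density <- function(events, t_start = 0, t_end, resolution = 60,
                           volume = probe_volume(), valid = NULL) {
  stopifnot_scalar(resolution, "resolution", positive = TRUE)
  stopifnot_scalar(volume, "volume", positive = TRUE)
  if (t_end <= t_start) stop("need t_end > t_start")
  nbin <- ceiling((t_end - t_start) / resolution)
  starts <- t_start + (seq_len(nbin) - 1L) * resolution
  occ <- numeric(nbin)
  for (i in seq_len(nrow(events))) {
    a <- events$start_s[i]
    b <- a + events$duration_s[i]
    lo <- max(1L, floor((a - t_start) / resolution) + 1L)
    hi <- min(nbin, floor((b - t_start) / resolution - 1e-12) + 1L)
    if (hi < lo) next
    for (j in lo:hi) {
      occ[j] <- occ[j] +
        max(0, min(b, starts[j] + resolution) - max(a, starts[j]))
    }
  }
  vf <- rep(1, nbin)
  if (!is.null(valid)) {
    if (is.data.frame(valid)) {
      m <- match(round(starts, 6), round(valid$interval_start_s, 6))
      if (anyNA(m)) stop("'valid' intervals do not match the density bins")
      vf <- as.numeric(valid$valid[m])
    } else {
      if (length(valid) != nbin) stop("'valid' must have one entry per bin")
      vf <- as.numeric(valid)
    }
  }
  dens <- ifelse(vf > 0, occ / (resolution * vf * volume), NA_real_)
  structure(
    data.frame(bin_start_s = starts, occupancy_s = occ,
               valid_fraction = vf, density_per_m3 = dens),
    resolution_s = resolution, volume = volume,
    class = c("density_series", "data.frame")
  )
}

#' Resample a density series to a coarser resolution
#'
#' Aggregates native bins into coarser ones by summing occupancy and valid
#' time, so that resampling and computing directly at the coarse resolution
#' give identical results, and repeated resampling is associative. The new
#' resolution must be an integer multiple of the current one.
#'
#' @param series A `density_series` from [aerial_density()].
#' @param resolution New bin width in seconds.
#' @return A new `density_series`.
#' @export
resample_density <- function(series, resolution) {
  old <- attr(series, "resolution_s")
  volume <- attr(series, "volume")
  ratio <- resolution / old
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("new resolution must be an integer multiple of the current one")
  }
  ratio <- as.integer(round(ratio))
  grp <- (seq_len(nrow(series)) - 1L) %/% ratio + 1L
  occ <- as.numeric(tapply(series$occupancy_s, grp, sum))
  valid_s <- as.numeric(tapply(series$valid_fraction * old, grp, sum))
  starts <- as.numeric(tapply(series$bin_start_s, grp, min))
  vf <- valid_s / resolution
  # A trailing partial group keeps its true span as the denominator.
  nlast <- sum(grp == max(grp))
  if (nlast < ratio) vf[length(vf)] <- valid_s[length(vf)] / (nlast * old)
  dens <- ifelse(valid_s > 0, occ / (valid_s * volume), NA_real_)
  structure(
    data.frame(bin_start_s = starts, occupancy_s = occ,
               valid_fraction = vf, density_per_m3 = dens),
    resolution_s = resolution, volume = volume,
    class = c("density_series", "data.frame")
  )
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf(
    "Aerial density series: %d bins of %.4g s, probe volume %.4g m^3\n",
    nrow(x), attr(x, "resolution_s"), attr(x, "volume")))
  cat(sprintf("  mean density %.4g /m^3 (%.1f%% of time valid)\n",
              mean(x$density_per_m3, na.rm = TRUE),
              100 * mean(x$valid_fraction)))
  invisible(x)
}

#' @export
plot.density_series <- function(x, ...) {
  graphics::plot(x$bin_start_s, x$density_per_m3, type = "s",
                 xlab = "time (s)", ylab = "aerial density (/m^3)", ...)
  invisible(x)
}
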