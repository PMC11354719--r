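#' Average trap count per day
#'
#' Trap collections arrive as cumulative catches over multi-day intervals.
#' The conventional abundance index divides each catch by the number of
#' days since the previous collection of that trap and averages across all
#' traps reporting on the same date.
#'
#' @param records Data frame with columns `trap_id`, `collection_date`
#'   (`Date` or ISO string), `count`, and either `days_since_previous` or
#'   enough per-trap history to derive it from consecutive dates.
#' @return Data frame with `collection_date` and `count_per_day` (mean over
#'   traps), plus `n_traps`.
#' @export
trap_count_per_day <- function(records) {
  records$collection_date <- as.Date(records$collection_date)
  if (any(records$count < 0)) stop("counts must be non-negative")
  if (is.null(records$days_since_previous)) {
    records <- records[order(records$trap_id, records$collection_date), ]
    records$days_since_previous <- stats::ave(
      as.numeric(records$collection_date), records$trap_id,
      FUN = function(d) c(NA, diff(d)))
    records <- records[!is.na(records$days_since_previous), ]
  }
  if (any(records$days_since_previous <= 0)) {
    stop("collection intervals must be positive")
  }
  rate <- records$count / records$days_since_previous
  agg <- stats::aggregate(rate,
                          by = list(collection_date =
                                      records$collection_date), FUN = mean)
  n <- stats::aggregate(rate,
                        by = list(collection_date =
                                    records$collection_date), FUN = length)
  data.frame(collection_date = agg$collection_date,
             count_per_day = agg$x, n_traps = n$x)
}

#' Align a density series to trap collection intervals
#'
#' Degrades the sensor's resolution to the traps': for each interval
#' between consecutive collection dates, the sensor value is the
#' valid-time-weighted mean aerial density over the interval, so both
#' systems share the same (artificial) temporal resolution. Intervals with
#' no valid sensor coverage are dropped with a warning.
#'
#' @param series A `density_series` whose `bin_start_s` is seconds since
#'   `origin`.
#' @param collection_dates Sorted vector of collection `Date`s.
#' @param origin `Date` corresponding to `bin_start_s = 0`.
#' @return Data frame of class `paired_series`: `interval_end`, and
#'   `density_mean` per interval.
#' @export
align_to_trap_intervals <- function(series, collection_dates,
                                    origin = as.Date("2022-01-01")) {
  collection_dates <- sort(as.Date(collection_dates))
  if (length(collection_dates) < 2L) stop("need at least two dates")
  res <- attr(series, "resolution_s")
  bin_day <- origin + floor(series$bin_start_s / 86400)
  out <- data.frame(interval_end = collection_dates[-1L],
                    density_mean = NA_real_)
  for (k in seq_len(nrow(out))) {
    sel <- bin_day >= collection_dates[k] & bin_day < collection_dates[k + 1L]
    w <- series$valid_fraction[sel]
    d <- series$density_per_m3[sel]
    ok <- is.finite(d) & w > 0
    if (any(ok)) {
      out$density_mean[k] <- sum(d[ok] * w[ok]) / sum(w[ok])
    }
  }
  drop <- !is.finite(out$density_mean)
  if (any(drop)) {
    warning(sprintf("%d interval(s) without valid sensor coverage dropped",
                    sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  class(out) <- c("paired_series", "data.frame")
  out
}

#' Correlation between sensor density and trap counts
#'
#' Pearson correlation between the interval-aligned aerial densities and
#' trap counts per day, with its two-sided test p-value, the squared
#' correlation, and the R-squared of the linear regression of counts on
#' density (identical to r^2 for simple linear regression; both reported
#' for completeness).
#'
#' @param density Numeric vector of interval mean densities.
#' @param counts Numeric vector of trap counts per day, same length.
#' @return List with `r`, `r_squared`, `regression_r_squared`, `p_value`,
#'   `n`.
#' @export
correlate_density_traps <- function(density, counts) {
  if (length(density) != length(counts)) stop("length mismatch")
  ok <- is.finite(density) & is.finite(counts)
  density <- density[ok]; counts <- counts[ok]
  if (length(density) < 3L) stop("need at least 3 pairs")
  if (stats::sd(density) == 0 || stats::sd(counts) == 0) {
    stop("zero variance in one of the series")
  }
  ct <- stats::cor.test(density, counts)
  fit <- stats::lm(counts ~ density)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       regression_r_squared = summary(fit)$r.squared,
       p_value = ct$p.value, n = length(density))
}
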