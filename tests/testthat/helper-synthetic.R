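# Shared fixtures, all generated in code at test time.

FS <- 30517

# One transit window with optional flat padding and sample noise.
make_transit <- function(fw, duration = 0.1, body = 0.006, wing = 0.0015,
                         fs = FS, v0 = 3, noise = 0, pad = 0) {
  p <- transit_params(duration = duration, wingbeat_freq = fw,
                      body_depth = body, wing_depth = wing)
  v <- simulate_transit(p, fs, v0, pad = pad)
  if (noise > 0) v <- v + stats::rnorm(length(v), 0, noise)
  v
}

# Test-local magnitude spectrum (Hann window), kept independent of the
# package's spectral helpers so spectral assertions have a second route.
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  mag <- Mod(stats::fft(x * w))[seq_len(n %/% 2)]
  list(freq = (seq_len(n %/% 2) - 1) * fs / n, mag = mag)
}

# Brute-force event scan: an independent plain-loop implementation of the
# detection contract (sub-threshold runs, gap bridging, expansion to the
# noise ceiling, duration filter) used as the oracle for detect_events.
brute_force_detect <- function(stream, config = detection_config(),
                               baseline = NULL) {
  v <- stream$samples
  fs <- stream$sampling_rate
  b <- if (is.null(baseline)) {
    if (length(v) / fs >= config$baseline_window) {
      estimate_baseline(stream, window = config$baseline_window)
    } else rep(stream$baseline_v0, length(v))
  } else rep(baseline, length.out = length(v))
  sd_n <- stats::mad(diff(v)) / sqrt(2)
  thr <- max(config$threshold_k * sd_n, config$threshold_floor_v)
  below <- v < b - thr
  runs <- list()
  i <- 1L
  while (i <= length(v)) {
    if (below[i]) {
      j <- i
      while (j < length(v) && below[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j + 1L)
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  # bridge gaps
  gap <- round(config$bridge_gap * fs)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] < gap) {
      merged[[length(merged)]][2] <- r[2]
    } else merged[[length(merged) + 1L]] <- r
  }
  # expand to the noise ceiling
  ceil <- max(3.5 * sd_n, 1e-9)
  wide_below <- v < b - ceil
  out <- lapply(merged, function(r) {
    a <- r[1]
    while (a > 1L && wide_below[a - 1L]) a <- a - 1L
    z <- r[2]
    while (z <= length(v) && wide_below[z]) z <- z + 1L
    c(a, z)
  })
  # merge overlaps, filter duration
  out <- out[!duplicated(vapply(out, paste, "", collapse = "-"))]
  res <- do.call(rbind, out)
  keep <- res[, 1]
  final <- list(res[1, ])
  if (nrow(res) > 1) {
    for (k in 2:nrow(res)) {
      last <- final[[length(final)]]
      if (res[k, 1] <= last[2]) {
        final[[length(final)]][2] <- max(last[2], res[k, 2])
      } else final[[length(final) + 1L]] <- res[k, ]
    }
  }
  res <- do.call(rbind, final)
  dur <- (res[, 2] - res[, 1]) / fs
  res <- res[dur >= config$min_duration, , drop = FALSE]
  data.frame(start = res[, 1], end = res[, 2])
}
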