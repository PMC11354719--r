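#' Parameters of a single simulated beam transit
#'
#' Describes one object crossing the beam: a body extinction envelope with a
#' Gaussian-like profile plus, for winged insects, a periodic wing-extinction
#' train at the wingbeat frequency and its harmonics. Wingless objects
#' (water droplets, debris) are obtained with `wingbeat_freq = 0` or
#' `wing_depth = 0`.
#'
#' @param start_time Event start within the stream, seconds.
#' @param duration Transit duration, seconds (> 0).
#' @param wingbeat_freq Wingbeat frequency in Hz; 0 for wingless objects.
#' @param body_depth Peak voltage drop attributable to the body, volts.
#' @param wing_depth Additional peak voltage drop attributable to the wings
#'   (wings fully extended), volts.
#' @param n_harmonics Number of harmonics in the wing waveform.
#' @param is_insect Logical ground-truth label.
#' @return A list of class `transit_params`.
#' @export
transit_params <- function(start_time = 0, duration, wingbeat_freq = 0,
                           body_depth, wing_depth = 0, n_harmonics = 3L,
                           is_insect = wing_depth > 0) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(start_time, "start_time")
  stopifnot_scalar(wingbeat_freq, "wingbeat_freq")
  stopifnot_scalar(body_depth, "body_depth")
  stopifnot_scalar(wing_depth, "wing_depth")
  if (wingbeat_freq < 0) stop("'wingbeat_freq' must be >= 0")
  if (body_depth < 0 || wing_depth < 0) stop("depths must be >= 0")
  structure(
    list(start_time = start_time, duration = duration,
         wingbeat_freq = wingbeat_freq, body_depth = body_depth,
         wing_depth = wing_depth, n_harmonics = as.integer(n_harmonics),
         is_insect = isTRUE(is_insect)),
    class = "transit_params"
  )
}

# Non-negative periodic wing waveform in [0, 1]: a harmonic cosine series
# with 1/k amplitudes, shifted and scaled so each cycle touches 0 exactly
# once (wings folded) and peaks at 1 (wings extended). Guarantees a
# harmonic-rich spectrum and non-negative wing extinction.
wing_waveform <- function(t, freq, n_harmonics) {
  k <- seq_len(max(1L, n_harmonics))
  p <- as.vector(cos(outer(2 * pi * freq * t, k)) %*% (1 / k))
  theta <- seq(0, 2 * pi, length.out = 4096L)
  pc <- as.vector(cos(outer(theta, k)) %*% (1 / k))
  (p - min(pc)) / (max(pc) - min(pc))
}

# Extinction time course of one transit on the sample grid 1..n (volts).
transit_extinction <- function(params, sampling_rate) {
  n <- max(2L, round(params$duration * sampling_rate))
  t <- (seq_len(n) - 0.5) / sampling_rate
  mid <- params$duration / 2
  env <- exp(-0.5 * ((t - mid) / (params$duration / 6))^2)
  ext <- params$body_depth * env
  if (params$wing_depth > 0 && params$wingbeat_freq > 0) {
    g <- wing_waveform(t - mid, params$wingbeat_freq, params$n_harmonics)
    ext <- ext + params$wing_depth * env * g
  }
  ext
}

#' Simulate the voltage window of a single transit
#'
#' Synthesises `V(t) = baseline - body_envelope(t) - wing_component(t)`:
#' the body envelope is a Gaussian profile (truncated at +/- 3 sd, with the
#' stated duration spanning 6 sd) of depth `body_depth`, and the wing
#' component is a non-negative harmonic train at `wingbeat_freq` scaled by
#' the same envelope, touching zero between wingbeats.
#'
#' @param params A [transit_params()] object.
#' @param sampling_rate Sampling rate in Hz.
#' @param baseline Background voltage V0 in volts.
#' @param pad Seconds of flat baseline prepended and appended.
#' @return Numeric voltage vector.
#' @examples
#' p <- transit_params(duration = 0.1, wingbeat_freq = 500,
#'                     body_depth = 0.006, wing_depth = 0.002)
#' v <- simulate_transit(p, 30517, 3)
#' @export
simulate_transit <- function(params, sampling_rate, baseline, pad = 0) {
  if (!inherits(params, "transit_params")) {
    stop("'params' must be a transit_params object")
  }
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(baseline, "baseline", positive = TRUE)
  if (params$body_depth + params$wing_depth >= baseline) {
    stop("total extinction depth must be smaller than the baseline voltage")
  }
  v <- baseline - transit_extinction(params, sampling_rate)
  if (pad > 0) {
    npad <- round(pad * sampling_rate)
    v <- c(rep(baseline, npad), v, rep(baseline, npad))
  }
  v
}

#' Scenario for a synthetic raw voltage stream
#'
#' Bundles everything needed to generate a reproducible stream: duration,
#' sampling, baseline, additive Gaussian sample noise, the transit events to
#' inject (either an explicit list of [transit_params()] or a rate plus a
#' parameter sampler), rain, and the probability that an event overlaps its
#' predecessor in the beam.
#'
#' @param duration Stream duration in seconds.
#' @param sampling_rate Sampling rate in Hz (default 30517).
#' @param baseline_v0 Background voltage in volts.
#' @param noise_sd Additive white Gaussian noise SD per sample, volts.
#' @param events Optional list of [transit_params()]; scheduled as given.
#' @param n_events Number of events to draw from `param_sampler`.
#' @param event_rate Alternative to `n_events`: mean events per second
#'   (the realised number is Poisson).
#' @param param_sampler Function `n -> data.frame` with columns `duration`,
#'   `wingbeat_freq`, `body_depth`, `wing_depth`, `n_harmonics`, `is_insect`.
#'   Defaults to [mosquito_transit_sampler()] for a mixed-sex population.
#' @param rain_mode One of `"none"`, `"light"`, `"heavy"`. Light rain adds
#'   sparse short droplet dips; heavy rain adds a dense droplet stream that
#'   keeps the baseline continuously perturbed.
#' @param overlap_probability Probability that an event is deliberately
#'   scheduled inside the span of its predecessor (default 1/800).
#' @param seed Integer seed; all generator output is a pure function of the
#'   scenario including this seed.
#' @param geometry [beam_geometry()] used for ground-truth cross-sections.
#' @return A list of class `stream_scenario`.
#' @export
stream_scenario <- function(duration, sampling_rate = 30517,
                            baseline_v0 = 3, noise_sd = 5e-5,
                            events = NULL, n_events = NULL, event_rate = NULL,
                            param_sampler = NULL,
                            rain_mode = c("none", "light", "heavy"),
                            overlap_probability = 1 / 800, seed = 1L,
                            geometry = beam_geometry()) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(baseline_v0, "baseline_v0", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (overlap_probability < 0 || overlap_probability > 1) {
    stop("'overlap_probability' must be in [0, 1]")
  }
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         baseline_v0 = baseline_v0, noise_sd = noise_sd, events = events,
         n_events = n_events, event_rate = event_rate,
         param_sampler = param_sampler %||% mosquito_transit_sampler(),
         rain_mode = match.arg(rain_mode),
         overlap_probability = overlap_probability,
         seed = as.integer(seed), geometry = geometry),
    class = "stream_scenario"
  )
}

#' Transit-parameter sampler for field mosquito populations
#'
#' Returns a sampler drawing wingbeat frequencies and wing-to-body
#' cross-section ratios from the field distributions measured for male
#' (524 +/- 65 Hz, ratio 0.19 +/- 0.05) and female (300 +/- 30 Hz, ratio
#' 0.27 +/- 0.07) mosquitoes. Ratios are truncated to (0, 0.95) and body
#' depths are drawn around 6 mV (roughly a 4 mm^2 body cross-section in a
#' 50.8 mm beam at 3 V baseline); the wing depth is then set so that the
#' true ratio `wing_depth / (wing_depth + body_depth)` matches the draw.
#' Transit durations are around 100 ms.
#'
#' @param sex `"male"`, `"female"`, or `"mixed"` (equal mixture).
#' @param body_depth_mean,body_depth_sd Body voltage-drop distribution, volts.
#' @param duration_mean,duration_sd Transit duration distribution, seconds.
#' @param n_harmonics Harmonics in the wing waveform.
#' @return A function `n -> data.frame` usable as the `param_sampler` of
#'   [stream_scenario()]; the data frame carries the true frequency and
#'   ratio draws in `wingbeat_freq` and `ratio_true`.
#' @export
mosquito_transit_sampler <- function(sex = c("mixed", "male", "female"),
                                     body_depth_mean = 0.006,
                                     body_depth_sd = 0.0015,
                                     duration_mean = 0.1,
                                     duration_sd = 0.02,
                                     n_harmonics = 3L) {
  sex <- match.arg(sex)
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
  }
  function(n) {
    sexes <- switch(sex,
      mixed = sample(c("male", "female"), n, replace = TRUE),
      rep(sex, n))
    male <- sexes == "male"
    fw <- numeric(n); ratio <- numeric(n)
    fw[male] <- rtrunc_norm(sum(male), 524, 65, 50, 890)
    fw[!male] <- rtrunc_norm(sum(!male), 300, 30, 50, 890)
    ratio[male] <- rtrunc_norm(sum(male), 0.19, 0.05, 0.005, 0.95)
    ratio[!male] <- rtrunc_norm(sum(!male), 0.27, 0.07, 0.005, 0.95)
    body <- rtrunc_norm(n, body_depth_mean, body_depth_sd,
                        body_depth_mean / 3, body_depth_mean * 3)
    data.frame(
      duration = rtrunc_norm(n, duration_mean, duration_sd,
                             max(0.05, duration_mean / 2), duration_mean * 2),
      wingbeat_freq = fw,
      body_depth = body,
      wing_depth = ratio / (1 - ratio) * body,
      n_harmonics = as.integer(n_harmonics),
      is_insect = TRUE,
      sex = sexes,
      ratio_true = ratio
    )
  }
}

# Droplet parameter draws for rain simulation: short smooth dips with no
# wing content. Rates chosen so light rain stays sparse while heavy rain
# keeps well over half of each second sub-baseline.
rain_rate <- function(rain_mode) {
  switch(rain_mode, none = 0, light = 2, heavy = 800)
}

droplet_params <- function(n) {
  data.frame(
    duration = stats::runif(n, 0.003, 0.015),
    wingbeat_freq = 0,
    body_depth = stats::runif(n, 0.05, 0.3) * 0.006 / 0.175,
    wing_depth = 0,
    n_harmonics = 1L,
    is_insect = FALSE
  )
}

#' Schedule the events of a stream scenario
#'
#' Draws event parameters and start times without synthesising any
#' waveform, returning the ground-truth ledger. Non-overlapping events are
#' placed uniformly at random without collision; with probability
#' `overlap_probability` an event is instead started inside the span of its
#' predecessor and flagged `overlap`. Rain droplets, when requested, are
#' added as an independent Poisson process.
#'
#' @param scenario A [stream_scenario()].
#' @return The ground-truth ledger: a data frame with one row per injected
#'   event (`event_id`, `start_s`, `end_s`, `duration_s`, `wingbeat_freq`,
#'   `body_depth`, `wing_depth`, `n_harmonics`, `is_insect`, `overlap`,
#'   `rain`, plus true cross-sections `sigma_w_true`, `sigma_b_true` and
#'   ratio `ratio_true`).
#' @export
schedule_events <- function(scenario) {
  if (!inherits(scenario, "stream_scenario")) {
    stop("'scenario' must be a stream_scenario object")
  }
  set.seed(scenario$seed)
  if (!is.null(scenario$events)) {
    pars <- do.call(rbind, lapply(scenario$events, function(p) {
      data.frame(duration = p$duration, wingbeat_freq = p$wingbeat_freq,
                 body_depth = p$body_depth, wing_depth = p$wing_depth,
                 n_harmonics = p$n_harmonics, is_insect = p$is_insect,
                 start_s = p$start_time)
    }))
    pars$overlap <- FALSE
    if (any(pars$start_s < 0 | pars$start_s + pars$duration >
            scenario$duration)) {
      stop("explicitly scheduled events extend past the stream duration")
    }
  } else {
    n <- scenario$n_events %||%
      stats::rpois(1L, (scenario$event_rate %||% 0) * scenario$duration)
    if (n > 0) {
      pars <- scenario$param_sampler(n)
      pars$overlap <- c(FALSE, stats::runif(n - 1) <
                          scenario$overlap_probability)[seq_len(n)]
      base <- which(!pars$overlap)
      occ <- sum(pars$duration[base])
      free <- scenario$duration - occ
      if (free <= 0) {
        stop("scheduled events exceed the stream duration")
      }
      gaps <- diff(c(0, sort(stats::runif(length(base), 0, free))))
      starts <- numeric(n)
      starts[base] <- cumsum(gaps) + cumsum(c(0, pars$duration[base]))[
        seq_along(base)]
      for (i in which(pars$overlap)) {
        host <- max(base[base < i], 1L)
        starts[i] <- starts[host] +
          stats::runif(1, 0, 0.8) * pars$duration[host]
        starts[i] <- min(starts[i],
                         max(0, scenario$duration - pars$duration[i]))
      }
      pars$start_s <- starts
    } else {
      pars <- NULL
    }
  }
  rate <- rain_rate(scenario$rain_mode)
  if (rate > 0) {
    nd <- stats::rpois(1L, rate * scenario$duration)
    if (nd > 0) {
      dp <- droplet_params(nd)
      dp$start_s <- stats::runif(nd, 0, scenario$duration - dp$duration)
      dp$overlap <- FALSE
      dp$rain <- TRUE
      if (!is.null(pars)) {
        pars$rain <- FALSE
        common <- intersect(names(pars), names(dp))
        pars <- rbind(pars[common], dp[common])
      } else {
        pars <- dp
      }
    }
  }
  if (is.null(pars) || nrow(pars) == 0L) {
    return(data.frame(event_id = integer(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric(),
                      wingbeat_freq = numeric(), body_depth = numeric(),
                      wing_depth = numeric(), n_harmonics = integer(),
                      is_insect = logical(), overlap = logical(),
                      rain = logical(), sigma_w_true = numeric(),
                      sigma_b_true = numeric(), ratio_true = numeric()))
  }
  if (is.null(pars$rain)) pars$rain <- FALSE
  pars <- pars[order(pars$start_s), , drop = FALSE]
  a <- scenario$geometry$area
  v0 <- scenario$baseline_v0
  out <- data.frame(
    event_id = seq_len(nrow(pars)),
    start_s = pars$start_s,
    end_s = pars$start_s + pars$duration,
    duration_s = pars$duration,
    wingbeat_freq = pars$wingbeat_freq,
    body_depth = pars$body_depth,
    wing_depth = pars$wing_depth,
    n_harmonics = pars$n_harmonics,
    is_insect = pars$is_insect,
    overlap = pars$overlap,
    rain = pars$rain,
    sigma_w_true = pars$wing_depth / v0 * a,
    sigma_b_true = pars$body_depth / v0 * a
  )
  out$ratio_true <- ifelse(out$sigma_w_true + out$sigma_b_true > 0,
                           out$sigma_w_true /
                             (out$sigma_w_true + out$sigma_b_true), NA_real_)
  if (!is.null(pars$sex)) out$sex <- pars$sex
  rownames(out) <- NULL
  out
}

#' Simulate a raw voltage stream with ground truth
#'
#' Generates the sampled stream for a scenario: every scheduled event's
#' extinction is subtracted from the baseline (overlapping transits sum
#' their extinction) and white Gaussian noise is added. Identical scenarios
#' (including the seed) yield bit-identical streams.
#'
#' @param scenario A [stream_scenario()].
#' @return A list with elements `stream` (a [raw_stream()]) and `ledger`
#'   (the ground-truth data frame from [schedule_events()]).
#' @export
simulate_stream <- function(scenario) {
  ledger <- schedule_events(scenario)
  fs <- scenario$sampling_rate
  n <- round(scenario$duration * fs)
  ext <- numeric(n)
  for (i in seq_len(nrow(ledger))) {
    row <- ledger[i, ]
    p <- transit_params(duration = row$duration_s,
                        wingbeat_freq = row$wingbeat_freq,
                        body_depth = row$body_depth,
                        wing_depth = row$wing_depth,
                        n_harmonics = row$n_harmonics,
                        is_insect = row$is_insect)
    e <- transit_extinction(p, fs)
    i0 <- round(row$start_s * fs)
    idx <- seq_along(e) + i0
    keep <- idx >= 1L & idx <= n
    ext[idx[keep]] <- ext[idx[keep]] + e[keep]
  }
  v <- scenario$baseline_v0 - ext
  if (scenario$noise_sd > 0) {
    set.seed(child_seed(scenario$seed, 1L))
    v <- v + stats::rnorm(n, 0, scenario$noise_sd)
  }
  list(
    stream = raw_stream(v, sampling_rate = fs,
                        baseline_v0 = scenario$baseline_v0),
    ledger = ledger
  )
}
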