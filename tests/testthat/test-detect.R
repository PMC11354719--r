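test_that("baseline estimation is exact on constant streams and immune to dips", {
  n <- 12 * FS
  st <- raw_stream(rep(3, n), FS)
  expect_true(all(estimate_baseline(st) == 3))
  # a 100 ms dip leaves the baseline estimate within 1% inside the dip
  v <- rep(3, n)
  dip <- make_transit(fw = 0, wing = 0, body = 0.5) - 3
  at <- 5 * FS + seq_along(dip)
  v[at] <- v[at] + dip
  b <- estimate_baseline(raw_stream(v, FS))
  expect_lt(max(abs(b[at] - 3)), 0.01 * 3)
  expect_error(estimate_baseline(raw_stream(rep(3, FS), FS)), "shorter")
})

test_that("baseline tracks slow drift to within noise", {
  n <- 60 * FS
  drift <- seq(3.0, 3.1, length.out = n)
  set.seed(2)
  st <- raw_stream(drift + rnorm(n, 0, 5e-5), FS)
  expect_lt(max(abs(estimate_baseline(st) - drift)), 5e-4)
})

test_that("flat streams produce no events", {
  expect_identical(nrow(detect_events(raw_stream(rep(3, FS), FS,
                                                 baseline_v0 = 3))), 0L)
  set.seed(3)
  noisy <- raw_stream(3 + rnorm(FS, 0, 5e-5), FS, baseline_v0 = 3)
  expect_identical(nrow(detect_events(noisy)), 0L)
})

test_that("a single injected dip is found with millisecond-exact bounds", {
  sc <- stream_scenario(duration = 4, noise_sd = 0, events = list(
    transit_params(start_time = 1.5, duration = 0.1, wingbeat_freq = 400,
                   body_depth = 0.01, wing_depth = 0.002)))
  s <- simulate_stream(sc)
  ev <- detect_events(s$stream)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$start_s - 1.5), 0.001)
  expect_lt(abs(ev$start_s + ev$duration_s - 1.6), 0.001)
})

test_that("events shorter than 10 ms are disregarded", {
  sc <- stream_scenario(duration = 2, noise_sd = 0, events = list(
    transit_params(start_time = 1, duration = 0.008, body_depth = 0.01)))
  s <- simulate_stream(sc)
  expect_identical(nrow(detect_events(s$stream)), 0L)
  # and no retained event is ever shorter than the configured minimum
  sc2 <- stream_scenario(duration = 6, noise_sd = 5e-5, seed = 9, events = lapply(
    seq(0.3, 5.3, by = 0.5), function(t0) {
      transit_params(start_time = t0, duration = runif(1, 0.004, 0.05),
                     wingbeat_freq = 350, body_depth = 0.008,
                     wing_depth = 0.002)
    }))
  ev2 <- detect_events(simulate_stream(sc2)$stream)
  expect_true(all(ev2$duration_s >= 0.010))
})

test_that("noise-free synthetic streams are recalled perfectly with exact bounds", {
  starts <- seq(0.5, 19, by = 0.75)
  sc <- stream_scenario(duration = 20, noise_sd = 0, events = lapply(
    starts, function(t0) {
      transit_params(start_time = t0, duration = 0.1, wingbeat_freq = 420,
                     body_depth = 0.02, wing_depth = 0.004)
    }))
  s <- simulate_stream(sc)
  ev <- detect_events(s$stream)
  expect_identical(nrow(ev), length(starts))
  expect_true(all(abs(ev$start_s - starts) < 0.001))
  expect_true(all(abs(ev$duration_s - 0.1) < 0.002))
})

test_that("lowering the threshold never decreases the candidate count", {
  set.seed(11)
  depths <- c(0.0006, 0.001, 0.0025, 0.006, 0.02)
  sc <- stream_scenario(duration = 8, noise_sd = 1e-4, seed = 11,
                        events = lapply(seq_along(depths), function(i) {
                          transit_params(start_time = i * 1.2,
                                         duration = 0.08,
                                         wingbeat_freq = 300,
                                         body_depth = depths[i],
                                         wing_depth = depths[i] / 4)
                        }))
  s <- simulate_stream(sc)
  counts <- vapply(c(14, 9, 6, 3), function(k) {
    cfg <- detection_config(threshold_k = k, threshold_floor_v = 2e-4)
    nrow(detect_events(s$stream, cfg))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("detection equals the brute-force scan on short streams", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    n_ev <- sample(2:5, 1)
    sc <- stream_scenario(duration = 3.2, noise_sd = 5e-5, seed = seed,
                          events = lapply(seq_len(n_ev), function(i) {
                            transit_params(start_time = 0.3 + (i - 1) * 0.7,
                                           duration = runif(1, 0.02, 0.2),
                                           wingbeat_freq = runif(1, 100, 700),
                                           body_depth = runif(1, 0.004, 0.02),
                                           wing_depth = 0.002)
                          }))
    s <- simulate_stream(sc)  # ~1e5 samples
    ev <- detect_events(s$stream)
    oracle <- brute_force_detect(s$stream)
    expect_identical(ev$start, oracle$start)
    expect_identical(ev$end, oracle$end)
  }
})

test_that("wing patterns separate insects from droplets and out-of-band signals", {
  set.seed(31)
  droplet <- make_transit(fw = 0, wing = 0, body = 0.01, noise = 5e-5)
  expect_identical(discriminate_insect(droplet, FS), "non_insect")
  insect <- make_transit(fw = 200, wing = 0.002, body = 0.006, noise = 5e-5)
  expect_identical(discriminate_insect(insect, FS), "insect")
  fast <- make_transit(fw = 950, wing = 0.002, body = 0.006, noise = 5e-5)
  expect_identical(discriminate_insect(fast, FS), "non_insect")
  expect_identical(discriminate_insect(rep(2.5, 2000), FS), "non_insect")
})

test_that("overlapping simultaneous transits merge into a single event", {
  sc <- stream_scenario(duration = 3, noise_sd = 0, events = list(
    transit_params(start_time = 1.00, duration = 0.1, wingbeat_freq = 300,
                   body_depth = 0.01, wing_depth = 0.002),
    transit_params(start_time = 1.05, duration = 0.1, wingbeat_freq = 500,
                   body_depth = 0.01, wing_depth = 0.002)))
  s <- simulate_stream(sc)
  ev <- detect_events(s$stream)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$duration_s - 0.15), 0.002)
})

test_that("heavy rain invalidates its interval while light rain does not", {
  heavy <- simulate_stream(stream_scenario(duration = 20, n_events = 2,
                                           rain_mode = "heavy", seed = 4))
  fh <- flag_invalid_intervals(heavy$stream, resolution = 10)
  expect_true(all(!fh$valid))
  expect_true(all(fh$occupancy > 0.5))

  light <- simulate_stream(stream_scenario(duration = 60, n_events = 3,
                                           rain_mode = "light", seed = 5))
  fl <- flag_invalid_intervals(light$stream, resolution = 30)
  expect_true(all(fl$valid))
  ev <- label_events(light$stream, detect_events(light$stream))
  expect_identical(sum(ev$label == "insect"), 3L)
  # surviving >= 10 ms droplets are individually rejected as non-insects
  expect_gt(sum(ev$label == "non_insect"), 0L)
  # and a clean stream is fully valid
  clean <- simulate_stream(stream_scenario(duration = 60, n_events = 3,
                                           seed = 5))
  expect_true(all(flag_invalid_intervals(clean$stream)$valid))
})
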