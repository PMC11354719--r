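test_that("transit parameter invariants are enforced", {
  expect_error(transit_params(duration = 0, body_depth = 0.1), "duration")
  expect_error(transit_params(duration = 0.1, body_depth = -1), "depths")
  expect_error(transit_params(duration = 0.1, body_depth = 0.1,
                              wingbeat_freq = -5), "wingbeat_freq")
  p <- transit_params(duration = 0.1, body_depth = 2, wing_depth = 1.5)
  expect_error(simulate_transit(p, FS, 3), "baseline")
})

test_that("wingless transits are pure smooth dips without in-band content", {
  v <- make_transit(fw = 0, wing = 0, body = 0.3)
  expect_equal(min(v), 3 - 0.3, tolerance = 1e-6)
  expect_true(all(v <= 3 + 1e-12))
  expect_identical(discriminate_insect(v, FS), "non_insect")
  expect_true(is.na(wingbeat_frequency(v, FS)))
})

test_that("the wing train puts its fundamental at the injected frequency", {
  v <- make_transit(fw = 500, duration = 0.1)
  f <- wingbeat_frequency(v, FS)
  expect_lt(abs(f - 500), 10)  # within the 1/0.1 s spectral resolution
})

test_that("harmonic structure matches a sum-of-sinusoids spectrum oracle", {
  # isolate the wing component as the difference between a winged and an
  # otherwise identical wingless transit, then inspect its raw spectrum
  v_full <- make_transit(fw = 300, duration = 0.15, wing = 0.002)
  v_body <- make_transit(fw = 300, duration = 0.15, wing = 0)
  wing <- v_body - v_full
  sp <- oracle_spectrum(wing, FS)
  peak_mag <- function(f0) {
    sel <- sp$freq > f0 - 25 & sp$freq < f0 + 25
    max(sp$mag[sel])
  }
  m <- c(peak_mag(300), peak_mag(600), peak_mag(900))
  floor_mag <- max(sp$mag[sp$freq > 1050 & sp$freq < 1150])
  expect_true(all(m > 10 * floor_mag))
  expect_true(all(diff(m) < 0))  # harmonic amplitudes decrease
})

test_that("streams are pure functions of the scenario and seed", {
  sc <- stream_scenario(duration = 3, n_events = 6, noise_sd = 5e-5,
                        seed = 42)
  s1 <- simulate_stream(sc)
  s2 <- simulate_stream(sc)
  expect_identical(s1$stream$samples, s2$stream$samples)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("an empty noise-free scenario yields a constant baseline stream", {
  sc <- stream_scenario(duration = 1, n_events = 0, noise_sd = 0)
  s <- simulate_stream(sc)
  expect_true(all(s$stream$samples == 3))
  expect_identical(nrow(s$ledger), 0L)
})

test_that("the scheduler conserves events and respects the stream end", {
  sc <- stream_scenario(duration = 600, n_events = 500, seed = 7)
  led <- schedule_events(sc)
  expect_identical(nrow(led), 500L)
  expect_true(all(led$end_s <= 600 + 1e-9))
  expect_true(all(led$start_s >= 0))
  expect_true(all(led$ratio_true >= 0 & led$ratio_true <= 1))
  # true cross-section ratio in the ledger follows from the true depths
  expect_equal(led$ratio_true,
               led$wing_depth / (led$wing_depth + led$body_depth),
               tolerance = 1e-12)
  # explicit events beyond the stream end are rejected
  bad <- stream_scenario(duration = 1, events = list(
    transit_params(start_time = 0.95, duration = 0.2, body_depth = 0.01)))
  expect_error(schedule_events(bad), "past the stream duration")
})

test_that("deliberate overlaps occur at the configured 1/800 rate", {
  sc <- stream_scenario(duration = 24000, n_events = 80000,
                        overlap_probability = 1 / 800, seed = 123)
  led <- schedule_events(sc)
  n_overlap <- sum(led$overlap)
  expected <- 80000 / 800
  expect_lt(abs(n_overlap - expected), 3.5 * sqrt(expected))
  # flagged events really start inside the span of an earlier event
  led <- led[order(led$start_s), ]
  ov <- which(led$overlap)
  inside <- vapply(ov, function(i) {
    any(led$start_s[-i] <= led$start_s[i] & led$end_s[-i] > led$start_s[i])
  }, logical(1))
  expect_gt(mean(inside), 0.95)
})

test_that("seasonal simulation follows the exponential-cubic curve", {
  flat <- seasonal_model(c(log(20), 0, 0), "negative_binomial", theta = 2)
  expect_equal(predict(flat, t = 1:100), rep(20, 100), tolerance = 1e-12)
  m <- seasonal_model(c(0, 0.1, -5e-4), "lognormal", sigma = 0.1)
  expect_equal(predict(m, t = 100), exp(5), tolerance = 1e-12)
  # NB family is overdispersed: sample variance exceeds the sample mean
  s <- simulate_season(flat, days = 2000, seed = 1)
  expect_gt(stats::var(s$count), 2 * mean(s$count))
  expect_error(seasonal_model(c(0, NA, 0), "lognormal", sigma = 1), "finite")
})
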