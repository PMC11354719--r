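test_that("wing/body separation is exact-by-construction and recovers envelopes", {
  # wingless input: wing component vanishes, body tracks the signal
  v0w <- make_transit(fw = 0, wing = 0)
  d0 <- separate_wing_body(v0w, FS)
  expect_true(d0$degenerate)
  expect_true(all(d0$wing == 0))
  expect_identical(d0$body, v0w)

  # winged input: reconstruction identity and 2% envelope recovery
  v <- make_transit(fw = 500, body = 0.006, wing = 0.0015)
  d <- separate_wing_body(v, FS)
  expect_false(d$degenerate)
  expect_equal(d$body - d$wing, v, tolerance = 1e-12)
  expect_lt(abs((3 - min(d$body)) - 0.006), 0.02 * 0.006)
  expect_lt(abs(max(d$wing_peak) - 0.0015), 0.02 * 0.0015)

  # too few cycles for separation is flagged degenerate
  short <- make_transit(fw = 60, duration = 0.03, wing = 0.002)
  expect_true(separate_wing_body(short, FS)$fw * 0.03 < 3 ||
                separate_wing_body(short, FS)$degenerate)
})

test_that("the 10%-lowest rule matches a brute-force sort oracle", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(10:5000, 1), mean = 3, sd = 0.1)
    k <- max(1, floor(length(x) / 10))
    oracle <- mean(x[order(x)][seq_len(k)])
    expect_equal(lowest_decile_mean(x), oracle, tolerance = 1e-14)
  }
  expect_error(lowest_decile_mean(rnorm(5)), "at least 10")
})

test_that("transit levels follow the decile rule on both traces", {
  # constant dip: VB is exactly the dip level
  flat <- list(body = rep(2.7, 1000), wing_peak = rep(0, 1000))
  lev <- transit_levels(flat, 3)
  expect_identical(lev$VB, 2.7)
  expect_identical(lev$Vw, 3)  # wingless: no wing extinction at all
  # winged event: levels within 2% of the injected peak depths
  v <- make_transit(fw = 500, body = 0.006, wing = 0.0015)
  lev2 <- transit_levels(separate_wing_body(v, FS), 3)
  expect_lt(abs((3 - lev2$VB) - 0.006), 0.02 * 0.006)
  expect_lt(abs((3 - lev2$Vw) - 0.0015), 0.03 * 0.0015)
})

test_that("extinction cross-sections follow the hand-evaluated formulas", {
  g <- beam_geometry(beam_diameter = 0.0508, path_length = 1)
  a <- pi * 0.0254^2
  s <- extinction_cross_sections(2.4, 2.7, 3.0, g)
  expect_equal(unname(s["sigma_b"]), 0.1 * a, tolerance = 1e-12)
  expect_equal(unname(s["sigma_w"]), 0.2 * a, tolerance = 1e-12)
  # no extinction
  s0 <- extinction_cross_sections(3, 3, 3, g)
  expect_identical(unname(s0["sigma_w"]), 0)
  # doubling the relative drop doubles the cross-section exactly
  s1 <- extinction_cross_sections(3, 2.85, 3, g)
  s2 <- extinction_cross_sections(3, 2.70, 3, g)
  expect_equal(unname(s2["sigma_b"]), 2 * unname(s1["sigma_b"]),
               tolerance = 1e-12)
  expect_warning(extinction_cross_sections(3.1, 3, 3, g), "clamping")
  expect_error(extinction_cross_sections(2.4, 2.7, 0, g), "positive")
})

test_that("the wing-to-body ratio is bounded and hand-checkable", {
  expect_identical(wing_body_ratio(0, 1e-4), 0)
  expect_identical(wing_body_ratio(2e-4, 2e-4), 0.5)
  expect_equal(wing_body_ratio(2e-4, 6e-4), 0.25, tolerance = 1e-12)
  expect_warning(r0 <- wing_body_ratio(0, 0))
  expect_true(is.na(r0))
  expect_error(wing_body_ratio(-1e-4, 1e-4), "non-negative")
  set.seed(43)
  r <- wing_body_ratio(runif(200, 0, 1e-3), runif(200, 1e-9, 1e-3))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("the fundamental is identified even when a harmonic dominates", {
  # constructed signal whose 600 Hz line is stronger than its 300 Hz one
  n <- round(0.12 * FS)
  t <- (seq_len(n) - 0.5) / FS
  env <- exp(-0.5 * ((t - 0.06) / 0.02)^2)
  train <- 0.35 * cos(2 * pi * 300 * t) + 1.0 * cos(2 * pi * 600 * t)
  train <- (train - min(train)) / diff(range(train))
  v <- 3 - 0.006 * env - 0.002 * env * train
  f <- wingbeat_frequency(v, FS)
  expect_lt(abs(f - 300), 10)
})

test_that("wingbeat frequency is recovered across the insect band", {
  set.seed(44)
  n <- 1000
  fw <- runif(n, 100, 700)
  err <- vapply(seq_len(n), function(i) {
    dur <- runif(1, 0.06, 0.15)
    v <- make_transit(fw[i], duration = dur, wing = 0.0018, noise = 5e-5)
    wingbeat_frequency(v, FS) - fw[i]
  }, numeric(1))
  expect_true(all(is.finite(err)))
  expect_lt(median(abs(err)), 10)  # well inside the spectral resolution
  expect_lt(mean(abs(err) > 0.3 * fw), 0.01)  # no harmonic confusion > 1%
})

test_that("feature extraction assembles the full per-event table", {
  sc <- stream_scenario(duration = 3, noise_sd = 5e-5, seed = 8, events = list(
    transit_params(start_time = 1, duration = 0.1, wingbeat_freq = 450,
                   body_depth = 0.006, wing_depth = 0.0015)))
  s <- simulate_stream(sc)
  ev <- label_events(s$stream, detect_events(s$stream))
  feats <- extract_features(s$stream, ev)
  expect_identical(nrow(feats), 1L)
  expect_lt(abs(feats$fw_hz - 450), 10)
  expect_lt(abs(feats$ratio_wb - 0.2), 0.02)
  expect_true(feats$sigma_w_m2 > 0 && feats$sigma_b_m2 > 0)
})
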