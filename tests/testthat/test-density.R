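test_that("probe volume matches hand evaluation and scaling laws", {
  g <- beam_geometry(0.0508, 36)
  expect_equal(probe_volume(g), pi * 0.0254^2 * 36, tolerance = 1e-12)
  expect_equal(probe_volume(g), 7.2966e-2, tolerance = 1e-4)
  g1 <- beam_geometry(0.0508, 1)
  expect_equal(probe_volume(g1), 2.0268e-3, tolerance = 1e-4)
  expect_equal(probe_volume(beam_geometry(2 * 0.0508, 36)),
               4 * probe_volume(g), tolerance = 1e-12)
  expect_error(beam_geometry(-1, 36), "positive")
})

test_that("aerial density is the occupancy integral of the events", {
  none <- data.frame(start_s = numeric(), duration_s = numeric())
  d0 <- aerial_density(none, 0, 120, 60, volume = 0.073)
  expect_true(all(d0$density_per_m3 == 0))

  # ten 100 ms transits in one 60 s bin, V = 0.073 m^3
  ten <- data.frame(start_s = seq(1, 50, length.out = 10), duration_s = 0.1)
  d10 <- aerial_density(ten, 0, 60, 60, volume = 0.073)
  expect_equal(d10$density_per_m3, 1.0 / (60 * 0.073), tolerance = 1e-12)

  # identical occupancy split into 100 x 10 ms gives identical density
  hundred <- data.frame(start_s = seq(0.5, 55, length.out = 100),
                        duration_s = 0.01)
  d100 <- aerial_density(hundred, 0, 60, 60, volume = 0.073)
  expect_equal(d100$density_per_m3, d10$density_per_m3, tolerance = 1e-12)

  # an event spanning a bin edge contributes its overlap to each bin
  split <- data.frame(start_s = 59.95, duration_s = 0.1)
  ds <- aerial_density(split, 0, 120, 60, volume = 0.073)
  expect_equal(ds$occupancy_s, c(0.05, 0.05), tolerance = 1e-9)
})

test_that("invalid time is removed from T, not zero-filled", {
  ev <- data.frame(start_s = c(10, 70), duration_s = c(0.1, 0.1))
  d <- aerial_density(ev, 0, 120, 60, volume = 0.073, valid = c(1, 0))
  expect_equal(d$density_per_m3[1], 0.1 / (60 * 0.073), tolerance = 1e-12)
  expect_true(is.na(d$density_per_m3[2]))
  # partial validity rescales the denominator
  dp <- aerial_density(ev[1, ], 0, 60, 60, volume = 0.073, valid = 0.5)
  expect_equal(dp$density_per_m3, 0.1 / (30 * 0.073), tolerance = 1e-12)
})

test_that("resampling aggregates by valid time and is associative", {
  set.seed(61)
  ev <- data.frame(start_s = runif(200, 0, 3600), duration_s = runif(200, 0.02, 0.3))
  valid <- rep(1, 60); valid[13] <- 0
  fine <- aerial_density(ev, 0, 3600, 60, volume = 0.073, valid = valid)
  hourly <- resample_density(fine, 3600)
  direct <- aerial_density(ev, 0, 3600, 3600, volume = 0.073,
                           valid = 59 / 60)
  expect_equal(hourly$density_per_m3, direct$density_per_m3,
               tolerance = 1e-9)
  expect_equal(hourly$valid_fraction, 59 / 60, tolerance = 1e-12)
  # resample(resample(x, 10 min), 1 h) == resample(x, 1 h)
  two_step <- resample_density(resample_density(fine, 600), 3600)
  expect_equal(two_step$density_per_m3, hourly$density_per_m3,
               tolerance = 1e-12)
  expect_error(resample_density(fine, 90), "integer multiple")
})

test_that("density eliminates the flight-speed bias that counts suffer", {
  # equal true aerial density, mean transit durations differing 5x
  set.seed(62)
  t_end <- 7200
  occupancy_target <- 60  # seconds of beam time in either population
  fast <- data.frame(start_s = runif(3000, 0, t_end - 1),
                     duration_s = rep(occupancy_target / 3000, 3000))
  slow <- data.frame(start_s = runif(600, 0, t_end - 1),
                     duration_s = rep(occupancy_target / 600, 600))
  df <- aerial_density(fast, 0, t_end, t_end, volume = 0.073)
  ds <- aerial_density(slow, 0, t_end, t_end, volume = 0.073)
  expect_equal(df$density_per_m3, ds$density_per_m3, tolerance = 1e-6)
  expect_equal(nrow(fast) / nrow(slow), 5, tolerance = 1e-12)
})

test_that("estimated density converges to injected occupancy over a stream", {
  starts <- seq(0.5, 58, by = 1.9)
  sc <- stream_scenario(duration = 60, noise_sd = 0, events = lapply(
    starts, function(t0) {
      transit_params(start_time = t0, duration = 0.09, wingbeat_freq = 400,
                     body_depth = 0.01, wing_depth = 0.002)
    }))
  s <- simulate_stream(sc)
  ev <- label_events(s$stream, detect_events(s$stream))
  est <- aerial_density(ev[ev$label == "insect", ], 0, 60, 60,
                        volume = 0.073)
  truth <- sum(s$ledger$duration_s) / (60 * 0.073)
  expect_equal(est$density_per_m3, truth, tolerance = 0.02)
})
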