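test_that("noiseless rhythmic genes are exactly cosine-valued at sampled ZTs", {
  spec <- rhythm_spec(mesor = 2, amplitude = 1, acrophase = 12, noise_sd = 0)
  sim <- simulate_expression_timecourse(
    expression_sim_config(1, 0, rhythm_specs = list(spec), seed = 1))
  tc <- sim$matrix
  expect_equal(dim(tc), c(1L, 18L))
  # peak column mean at ZT12, trough at ZT24 (cosine half-period away)
  expect_equal(unname(mean(tc$values[1, tc$sample_zt == 12])), 3.0, tolerance = 1e-12)
  expect_equal(unname(mean(tc$values[1, tc$sample_zt == 24])), 1.0, tolerance = 1e-12)
  expected <- 2 + cos(2 * pi * (tc$sample_zt - 12) / 24)
  expect_equal(unname(tc$values[1, ]), expected, tolerance = 1e-12)
})

test_that("arrhythmic genes are flat at their mesor without noise", {
  cfg <- expression_sim_config(0, 5, noise_sd_frac = 0, seed = 3)
  sim <- simulate_expression_timecourse(cfg)
  expect_true(all(apply(sim$matrix$values, 1, function(r) diff(range(r))) == 0))
  expect_equal(unname(sim$matrix$values[, 1]), sim$truth$mesor)
  expect_false(any(sim$truth$rhythmic))
})

test_that("expression simulator is bit-identical under the same seed", {
  cfg <- expression_sim_config(10, 10, seed = 1)
  a <- simulate_expression_timecourse(cfg)
  b <- simulate_expression_timecourse(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
})

test_that("expression config rejects invalid designs", {
  expect_error(rhythm_spec(mesor = 0, amplitude = 1, acrophase = 0), "mesor")
  expect_error(rhythm_spec(mesor = -2, amplitude = 1, acrophase = 0), "mesor")
  expect_error(expression_sim_config(1, 1, timepoints = numeric(0)), "empty")
  expect_error(expression_sim_config(1, 1, timepoints = c(4, 4, 8)), "increasing")
  expect_error(expression_sim_config(1, 1, replicates = 0), "replicates")
})

test_that("trace simulator truth peaks follow period and perturbation", {
  sim <- simulate_luminescence_trace(
    trace_sim_config(duration = 72, period = 24, phase = 0))
  expect_equal(sim$truth$peak_times, c(0, 24, 48, 72))

  sim22 <- simulate_luminescence_trace(trace_sim_config(duration = 96, period = 22, phase = 0))
  expect_true(all(diff(sim22$truth$peak_times) == 22))

  # +10 h advance at t = 40: first post-perturbation truth peak is 10 h
  # earlier than the unperturbed extrapolation
  base <- simulate_luminescence_trace(trace_sim_config(duration = 96, phase = 0))
  pert <- simulate_luminescence_trace(trace_sim_config(
    duration = 96, phase = 0, perturbation_time = 40, perturbation_phase_shift = 10))
  post <- pert$truth$peak_times[pert$truth$peak_times >= 40][1]
  expect_true(any(abs(base$truth$peak_times - (post + 10)) < 1e-9))

  expect_error(trace_sim_config(dt = 0), "dt")
  expect_error(trace_sim_config(duration = 30, period = 24), "two periods")
})

test_that("trace counts follow the damped-cosine model and seeds reproduce", {
  cfg <- trace_sim_config(duration = 48, period = 24, amplitude = 10,
                          baseline = 100, baseline_trend = 0.5,
                          damping_rate = 0.02, phase = 6, noise_sd = 0)
  sim <- simulate_luminescence_trace(cfg)
  t <- sim$trace$t
  expect_equal(sim$trace$counts,
               100 + 0.5 * t + exp(-0.02 * t) * 10 * cos(2 * pi * (t - 6) / 24),
               tolerance = 1e-12)
  noisy <- trace_sim_config(duration = 48, noise_sd = 3, seed = 5)
  expect_identical(simulate_luminescence_trace(noisy)$trace$counts,
                   simulate_luminescence_trace(noisy)$trace$counts)
})

test_that("void simulator emits capacity-sized events conserving production", {
  # constant production 50 ul/h, constant capacity 200 ul, 1 day: 1200/200
  cfg <- void_sim_config(days = 1, production_rate = 50,
                         production_modulation = 0, capacity_mesor = 200,
                         capacity_modulation = 0, event_jitter_sd = 0)
  sim <- simulate_void_events(cfg)
  expect_equal(nrow(sim$events), 6L)
  expect_equal(sim$events$volume_ul, rep(200, 6))
  expect_equal(sim$events$t_h, c(4, 8, 12, 16, 20, 24), tolerance = 0.02)

  # volume conservation within one capacity, with modulation and jitter
  cfg2 <- void_sim_config(days = 3, capacity_modulation = 0.4,
                          event_jitter_sd = 10, seed = 2)
  sim2 <- simulate_void_events(cfg2)
  max_cap <- cfg2$capacity_mesor * (1 + cfg2$capacity_modulation)
  expect_lt(abs(sum(sim2$events$volume_ul) - sim2$truth$total_production), max_cap)

  # capacity low in the dark phase: smaller voids in the dark
  cfg3 <- void_sim_config(days = 3, capacity_modulation = 0.5, seed = 3)
  sim3 <- simulate_void_events(cfg3)
  dark <- is_dark(sim3$events$zt)
  expect_lt(mean(sim3$events$volume_ul[dark]), mean(sim3$events$volume_ul[!dark]))

  expect_error(void_sim_config(production_rate = 0, production_modulation = 0),
               "production")
  expect_error(void_sim_config(capacity_modulation = 1), "modulation")
})

test_that("calibration pairs lie on the line and span the stain range", {
  pairs <- simulate_calibration_pairs(slope = 5, intercept = 0, n = 20)
  expect_equal(pairs$volume_ul, 5 * pairs$area_cm2)
  expect_true(all(pairs$volume_ul >= 10 & pairs$volume_ul <= 800))
  expect_equal(range(pairs$volume_ul), c(10, 800))
  # a 40 cm^2 stain at 5 ul/cm^2 is a 200 ul void
  mid <- simulate_calibration_pairs(slope = 5, n = 3, volume_range = c(100, 300))
  expect_true(any(mid$area_cm2 == 40 & mid$volume_ul == 200))
  a <- simulate_calibration_pairs(5, 2, n = 10, noise_sd = 4, seed = 7)
  b <- simulate_calibration_pairs(5, 2, n = 10, noise_sd = 4, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_calibration_pairs(5, n = 1), "2 calibration pairs")
})
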