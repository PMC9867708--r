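test_that("standard curve fits the calibration line and rejects bad input", {
  pairs <- simulate_calibration_pairs(slope = 5, intercept = 0, n = 10)
  curve <- fit_standard_curve(pairs)
  expect_equal(curve$slope, 5, tolerance = 1e-9)
  expect_equal(curve$intercept, 0, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-12)

  noisy <- simulate_calibration_pairs(slope = 5, intercept = 2, n = 20,
                                      noise_sd = 5, seed = 1)
  cn <- fit_standard_curve(noisy)
  expect_lt(abs(cn$slope - 5) / 5, 0.05)

  expect_error(fit_standard_curve(data.frame(area_cm2 = c(1, 1),
                                             volume_ul = c(5, 9))), "identical")
  expect_error(fit_standard_curve(noisy[1, ]), "2 calibration")
  set.seed(2)
  junk <- data.frame(area_cm2 = runif(20, 0, 100), volume_ul = runif(20, 10, 800))
  expect_error(fit_standard_curve(junk), "recalibrate")
})

test_that("stains convert to timed, calibrated events with range flags", {
  curve <- fit_standard_curve(simulate_calibration_pairs(slope = 5, n = 10))
  raw <- data.frame(position_cm = c(25, 100, 2), area_cm2 = c(30, 180, 1))
  ev <- stain_to_event(raw, curve, paper_speed = 10, start_zt = 14)
  expect_equal(ev$t_h, c(0.2, 2.5, 10))          # sorted by time
  expect_equal(ev$volume_ul, c(5, 150, 900))
  expect_identical(ev$extrapolated, c(TRUE, FALSE, TRUE))  # outside 10-800 kept
  expect_equal(ev$zt[2], 16.5)

  # noiseless simulation round trip: area -> volume inverts the calibration
  sim <- simulate_calibration_pairs(slope = 5, intercept = 3, n = 5)
  ev2 <- stain_to_event(data.frame(position_cm = 1:5, area_cm2 = sim$area_cm2),
                        fit_standard_curve(sim))
  expect_equal(sort(ev2$volume_ul), sort(sim$volume_ul), tolerance = 1e-9)

  expect_error(stain_to_event(data.frame(position_cm = -1, area_cm2 = 2), curve),
               "position")
})

test_that("events land in the dark-onset-anchored 8-h bins exactly once", {
  ev <- data.frame(t_h = c(0, 11, 20, 36), zt = c(14, 1, 10, 2),
                   volume_ul = rep(100, 4))
  attr(ev, "start_zt") <- 14
  b <- bin_events(ev)
  expect_equal(as.character(b$bin), c("ZT14", "ZT22", "ZT14", "ZT6"))
  expect_equal(b$day, c(1L, 1L, 1L, 2L))

  # partition property: every ZT belongs to exactly one default bin
  set.seed(91)
  rand <- data.frame(t_h = runif(1000, 0, 72), volume_ul = 100)
  attr(rand, "start_zt") <- 14
  br <- bin_events(rand)
  expect_false(anyNA(br$bin))
  expect_equal(sum(table(br$bin)), 1000L)
  # edge goes to the later bin
  edge <- data.frame(t_h = 4, zt = 18, volume_ul = 1)
  attr(edge, "start_zt") <- 14
  expect_equal(as.character(bin_events(edge)$bin), "ZT22")

  expect_error(bin_spec(centers = c(14, 18)), "overlap")
})

test_that("bin summaries conserve volume and flag empty cells", {
  ev <- data.frame(t_h = seq(0.2, 3.8, length.out = 10),  # all within ZT14-18
                   volume_ul = rep(200, 10))
  attr(ev, "start_zt") <- 14
  sm <- summarize_bins(bin_events(ev))
  z14 <- sm[sm$bin == "ZT14", ]
  expect_equal(z14$n_voids, 10L)
  expect_equal(z14$mean_ul_per_void, 200)
  expect_equal(z14$total_ul, 2000)
  expect_equal(z14$ul_per_h, 250)  # 2000 ul over the 8-h bin
  expect_true(all(sm$empty[sm$bin != "ZT14"]))
  expect_true(all(is.na(sm$mean_ul_per_void[sm$empty])))

  # conservation through binning, with a realistic stream
  sim <- simulate_void_events(void_sim_config(days = 3, event_jitter_sd = 8,
                                              seed = 5))
  sm2 <- summarize_bins(bin_events(sim$events))
  expect_equal(sum(sm2$total_ul), sum(sim$events$volume_ul))
})

test_that("reference normalization makes ZT6 the unit and scales the rest", {
  sm <- data.frame(day = c(1, 1, 1), bin = c("ZT14", "ZT22", "ZT6"),
                   n_voids = c(4L, 4L, 4L), total_ul = c(600, 1000, 1200),
                   mean_ul_per_void = c(150, 250, 300),
                   ul_per_h = c(75, 125, 150), empty = FALSE)
  nr <- normalize_to_reference(sm)
  expect_equal(nr$ratio[nr$bin == "ZT6"], 1)
  expect_equal(nr$ratio[nr$bin == "ZT14"], 0.5)

  same <- sm; same$mean_ul_per_void <- 250
  expect_equal(normalize_to_reference(same)$ratio, rep(1, 3))

  gone <- sm[sm$bin != "ZT6", ]
  expect_error(normalize_to_reference(gone), "reference")
})

test_that("the configured capacity modulation is recovered from bin ratios", {
  evs <- cohort_events(n_subjects = 5, days = 3, capacity_modulation = 0.4,
                       jitter = 10, seed0 = 0)
  per_subj <- vapply(unique(evs$subject), function(s) {
    e <- evs[evs$subject == s, ]
    attr(e, "start_zt") <- 14
    nr <- normalize_to_reference(summarize_bins(bin_events(e)))
    mean(nr$ratio[nr$bin == "ZT14"])
  }, numeric(1))
  m_hat <- modulation_from_bin_ratio(mean(per_subj))
  expect_lt(abs(m_hat - 0.4) / 0.4, 0.1)
  expect_equal(modulation_from_bin_ratio(1), 0)
})

test_that("the diurnal rhythm flag detects modulation and stays quiet at null", {
  evs <- cohort_events(capacity_modulation = 0.5, seed0 = 100)
  flag <- suppressMessages(diurnal_rhythm_flag(summarize_bins(bin_events(evs))))
  expect_true(flag$rhythm_present)
  expect_equal(nrow(flag$contrasts), 2L)

  # type-I control: flat capacity should rarely trip the flag
  hits <- vapply(1:40, function(r) {
    e <- cohort_events(capacity_modulation = 0, seed0 = 2000 + r * 10)
    suppressMessages(diurnal_rhythm_flag(summarize_bins(bin_events(e))))$rhythm_present
  }, logical(1))
  expect_lte(mean(hits), 0.15)

  one_bin <- summarize_bins(bin_events(evs))
  one_bin <- one_bin[one_bin$bin == "ZT14", ]
  expect_error(diurnal_rhythm_flag(one_bin), "2 bins")
})
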