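test_that("pre-noise vertical forces conserve body weight at every sample", {
  p <- virtual_participant(72.7)
  rec <- simulate_session(p, quick_config(seed = 11, duration = 120))
  truth <- attr(rec, "sim_truth")
  total_frac <- truth$frac_left + truth$frac_right + truth$arm_frac +
    truth$residual_frac
  expect_equal(max(abs(total_frac - 1)), 0, tolerance = 1e-12)
  expect_lte(truth$residual_frac, 0.03)
  # noisy recorded streams: residual share plus bounded sensor noise
  mg <- rec$body_mass * 9.81
  fz_sum <- rec$streams$plate_left$values[, "Fz"] +
    rec$streams$plate_right$values[, "Fz"] +
    abs(rec$streams$rail_left$values[, "Fz"]) +
    abs(rec$streams$rail_right$values[, "Fz"]) +
    truth$residual_frac * mg
  noise_sd_sum <- 2 * p$noise_force_sd        # four independent 5 N channels
  expect_lt(max(abs(fz_sum - mg)), 0.03 * mg + 5 * noise_sd_sum)
})

test_that("identical participant, config and seed give identical recordings", {
  p <- virtual_participant(57.2)
  a <- simulate_session(p, quick_config(seed = 99, duration = 60))
  b <- simulate_session(p, quick_config(seed = 99, duration = 60))
  for (nm in names(a$streams))
    expect_identical(a$streams[[nm]]$values, b$streams[[nm]]$values)
  c_ <- simulate_session(p, quick_config(seed = 100, duration = 60))
  expect_false(identical(a$streams$plate_left$values,
                         c_$streams$plate_left$values))
})

test_that("detected peaks alternate sides at half-period spacing", {
  p <- virtual_participant(83.3, habituation_start = 1)  # no ramp-in
  rec <- simulate_session(p, quick_config(seed = 5, duration = 300))
  cyc <- analyze_session(rec)
  expect_gt(nrow(cyc), 20)
  sides <- cyc$side
  expect_true(all(sides[-1] != sides[-length(sides)]))
  gaps <- diff(cyc$peak_time)
  P <- schedule_period(stim_schedule())
  expect_true(all(abs(gaps - P / 2) < 2.5))
})

test_that("the pipeline recovers the configured support fraction", {
  p <- virtual_participant(83.3, mature_support_frac = 0.75)
  means <- vapply(1:4, function(s) {
    rec <- simulate_session(p, quick_config(seed = s, duration = 900))
    cyc <- analyze_session(rec)
    mean(cyc$peak_bw_pct[cyc$peak_time > p$habituation +
                           quick_config(seed = 1)$pre_exercise])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 75), max(2 * se, 0.5))
})

test_that("improvement profile holds early, saturates late, never decreases", {
  p <- virtual_participant(83.3)
  expect_equal(participant_profile(p, 1), p$improvement_early)
  expect_equal(participant_profile(p, 5), p$improvement_early)
  expect_equal(participant_profile(p, 8), p$improvement_late)
  expect_equal(participant_profile(p, 40), p$improvement_late)
  prof <- participant_profile(p, 1:20)
  expect_true(all(diff(prof) >= 0))
  sw <- sway_profile(p, 1:20)
  expect_true(all(diff(sw) >= 0))
  expect_equal(sway_profile(p, 1), p$sway_half_angle_early)
  expect_error(participant_profile(p, 0), ">= 1")
})

test_that("longitudinal series are deterministic in the master seed", {
  p <- virtual_participant(72.7)
  cfg <- quick_config(seed = 1, duration = 60)
  series <- simulate_longitudinal(p, 3, cfg, master_seed = 7)
  expect_length(series, 3L)
  expect_equal(vapply(series, function(r) r$session_index, integer(1)), 1:3)
  series2 <- simulate_longitudinal(p, 3, cfg, master_seed = 7)
  expect_identical(series[[2]]$streams$plate_left$values,
                   series2[[2]]$streams$plate_left$values)
  series3 <- simulate_longitudinal(p, 3, cfg, master_seed = 8)
  expect_false(identical(series[[1]]$streams$plate_left$values,
                         series3[[1]]$streams$plate_left$values))
})

test_that("scaling the sway half-angle scales the measured ROM", {
  p1 <- virtual_participant(83.3, habituation_start = 1,
                            noise_force_sd = 0, noise_moment_sd = 0,
                            noise_marker_sd = 0)
  cfg <- quick_config(seed = 2, duration = 240,
                      sway_half_angle = 4)
  cfg2 <- quick_config(seed = 2, duration = 240,
                       sway_half_angle = 8)
  rom1 <- range_of_motion(analyze_session(simulate_session(p1, cfg)))
  rom2 <- range_of_motion(analyze_session(simulate_session(p1, cfg2)))
  expect_gt(length(rom1), 5)
  expect_equal(mean(rom2) / mean(rom1), 2, tolerance = 0.02)
})

test_that("infeasible support fractions are rejected", {
  expect_error(virtual_participant(80, mature_support_frac = 0.95,
                                   arm_support_frac = 0.2),
               "infeasible")
  p <- virtual_participant(80)
  expect_error(simulate_session(p, quick_config(seed = 1, duration = 60,
                                                support_frac = 0.97)),
               "infeasible")
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(seed = 1, duration = 5), "too short")
})

test_that("simulated recordings round-trip through the container", {
  p <- virtual_participant(57.2)
  rec <- simulate_session(p, quick_config(seed = 21, duration = 30))
  path <- file.path(tempdir(), "sim_rt")
  write_session(rec, path)
  back <- read_session(path)
  expect_equal(back$streams$plate_right$values, rec$streams$plate_right$values,
               tolerance = 1e-6)
  expect_equal(back$events$label, rec$events$label)
  unlink(path, recursive = TRUE)
})
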