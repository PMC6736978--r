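test_that("envelope plateaus and ramps follow the cyclic pattern", {
  s <- stim_schedule(5, 3, 1, off_pct = 0)
  expect_equal(envelope_level(s, "LEFT", 2.5), 1.0)          # mid ON
  expect_equal(envelope_level(s, "LEFT", 5.5), 0.5)          # ramp-down mid
  expect_equal(envelope_level(s, "LEFT", 7.5), 0.0)          # mid OFF
  s50 <- stim_schedule(5, 3, 1, off_pct = 0.5)
  expect_equal(envelope_level(s50, "LEFT", 7.5), 0.5)        # resting level
  expect_equal(envelope_level(s50, "LEFT", 2.5), 1.0)
})

test_that("envelope is periodic, bounded and half-period shifted", {
  set.seed(7)
  for (rep in 1:5) {
    s <- stim_schedule(runif(1, 2, 8), runif(1, 1, 5), runif(1, 0.5, 2),
                       off_pct = runif(1, 0, 0.8))
    P <- schedule_period(s)
    t <- runif(50, 0, 3 * P)
    for (g in c("LEFT", "RIGHT")) {
      lv <- envelope_level(s, g, t)
      expect_true(all(lv >= s$off_pct - 1e-12 & lv <= 1 + 1e-12))
      expect_equal(envelope_level(s, g, t + P), lv, tolerance = 1e-9)
    }
    expect_equal(envelope_level(s, "RIGHT", t),
                 envelope_level(s, "LEFT", t + P / 2), tolerance = 1e-9)
  }
})

test_that("schedule geometry is classified as tiling, overlap or gap", {
  v <- validate_schedule(stim_schedule(5, 3, 1))
  expect_equal(v$period, 10)
  expect_equal(v$geometry, "tiling")
  expect_equal(v$mismatch, 0)
  v <- validate_schedule(stim_schedule(6, 3, 1))
  expect_equal(v$geometry, "overlap")
  expect_equal(v$mismatch, 1)
  v <- validate_schedule(stim_schedule(4, 3, 1))
  expect_equal(v$geometry, "gap")
  expect_equal(v$mismatch, 1)
  expect_error(stim_schedule(-1, 3, 1), "positive")
})

test_that("tiling keeps exactly one group at full stimulation", {
  # sample away from the measure-zero plateau boundaries
  t <- seq(0.005, 29.995, by = 0.01)
  s <- stim_schedule(5, 3, 1, off_pct = 0)
  L <- envelope_level(s, "LEFT", t); R <- envelope_level(s, "RIGHT", t)
  expect_true(all((L == 1) + (R == 1) == 1))         # one and only one ON
  # overlap: both sides simultaneously at full level for part of the cycle
  s_ov <- stim_schedule(6, 3, 1)
  L <- envelope_level(s_ov, "LEFT", t); R <- envelope_level(s_ov, "RIGHT", t)
  expect_true(any(L == 1 & R == 1))
  # gap: instants where neither side is at full level
  s_gap <- stim_schedule(4, 3, 1)
  L <- envelope_level(s_gap, "LEFT", t); R <- envelope_level(s_gap, "RIGHT", t)
  expect_true(any(L < 1 & R < 1))
})

test_that("pulse trains run at the device rate with envelope-scaled widths", {
  s <- stim_schedule(5, 3, 1, on_pulse_width = 300)
  pt <- generate_pulse_train(s, 1, 0, 1)            # inside LEFT ON plateau
  expect_equal(nrow(pt), 30L)                        # 1 s x 30 Hz
  expect_equal(diff(pt$time), rep(1 / 30, 29L), tolerance = 1e-12)
  expect_true(all(pt$width == 300))                  # envelope = 1
  expect_true(all(pt$amplitude == 138))
  # during the OFF plateau with off_pct = 0 no pulses are emitted
  pt_off <- generate_pulse_train(s, 1, 6.2, 8.8)
  expect_equal(nrow(pt_off), 0L)
  expect_error(generate_pulse_train(
    stim_schedule(channel_group = c("LEFT", rep("UNASSIGNED", 15))), 2, 0, 1),
    "unassigned")
})

test_that("pulse count over whole periods scales linearly", {
  s <- stim_schedule(5, 3, 1, off_pct = 0.25)
  P <- schedule_period(s)
  n1 <- nrow(generate_pulse_train(s, 1, 0, P))
  n3 <- nrow(generate_pulse_train(s, 1, 0, 3 * P))
  expect_equal(n3, 3L * n1)
})

test_that("continuous mode holds a level and hands over without a jump", {
  cm <- continuous_mode(1.0)
  expect_true(all(cm$envelope(c(0, 3.3, 99)) == 1))
  silent <- continuous_mode(0)
  s <- stim_schedule(5, 3, 1)
  expect_equal(nrow(generate_pulse_train(s, 1, 0, 2,
                                         envelope = silent$envelope)), 0L)
  expect_error(continuous_mode(1.5), "configuration")
  # switch instant lands where the cyclic envelope equals the held level
  for (lvl in c(1, 0.6)) {
    tsw <- cyclic_switch_time(s, "LEFT", t = 12.3, level = lvl)
    expect_gte(tsw, 12.3)
    expect_equal(envelope_level(s, "LEFT", tsw), lvl, tolerance = 1e-9)
  }
  tswR <- cyclic_switch_time(s, "RIGHT", t = 0, level = 1)
  expect_equal(envelope_level(s, "RIGHT", tswR), 1)
})

test_that("schedules load from JSON configs", {
  path <- file.path(tempdir(), "sched.json")
  jsonlite::write_json(list(on_time = 4, off_time = 2, transition_time = 1,
                            off_pct = 0.2, on_pulse_width = 250),
                       path, auto_unbox = TRUE)
  s <- read_schedule(path)
  expect_equal(s$on_time, 4)
  expect_equal(s$off_pct, 0.2)
  expect_equal(schedule_period(s), 8)
  unlink(path)
})
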