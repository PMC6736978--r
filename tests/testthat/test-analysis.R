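# bell-shaped bump helper used to build synthetic GRF traces
bump <- function(t, centre, height, width = 1) height * exp(-((t - centre) / width)^2)

test_that("cycle peaks respect the threshold and separation rules", {
  m <- 80; mg <- m * 9.81
  t <- seq(0, 60, by = 0.01)
  # constant 40% BW: no local maxima above threshold
  s <- timed_stream("fz", t, matrix(0.4 * mg, length(t)), "Fz", "N", 100)
  expect_equal(nrow(detect_cycle_peaks(s, m)), 0L)
  # two 60% BW bumps 6 s apart: both kept
  v <- bump(t, 20, 0.6 * mg) + bump(t, 26, 0.6 * mg)
  s <- timed_stream("fz", t, matrix(v, dimnames = list(NULL, "Fz")), "Fz", "N", 100)
  pk <- detect_cycle_peaks(s, m)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$time, c(20, 26), tolerance = 0.02)
  # two bumps 3 s apart, 60% and 70%: only the larger survives
  v <- bump(t, 20, 0.6 * mg) + bump(t, 23, 0.7 * mg)
  s <- timed_stream("fz", t, matrix(v, dimnames = list(NULL, "Fz")), "Fz", "N", 100)
  pk <- detect_cycle_peaks(s, m)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$bw_pct, 70, tolerance = 1)
})

test_that("plateau maxima report their first sample and edges are dropped", {
  m <- 80; mg <- m * 9.81
  t <- seq(0, 30, by = 0.1)
  v <- rep(0.2 * mg, length(t))
  v[t >= 14 & t <= 15] <- 0.8 * mg             # flat-topped peak
  s <- timed_stream("fz", t, matrix(v, dimnames = list(NULL, "Fz")), "Fz", "N", 10)
  pk <- detect_cycle_peaks(s, m)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 14)
  # a peak 2 s from the end of the trace is edge-truncated
  v2 <- bump(t, 28, 0.9 * mg)
  s2 <- timed_stream("fz", t, matrix(v2, dimnames = list(NULL, "Fz")), "Fz", "N", 10)
  expect_equal(nrow(detect_cycle_peaks(s2, m)), 0L)
  kept <- detect_cycle_peaks(s2, m, edge_policy = "keep")
  expect_equal(nrow(kept), 1L)
  expect_true(kept$edge_truncated)
})

test_that("peaks inside excluded event intervals are dropped", {
  m <- 80; mg <- m * 9.81
  t <- seq(0, 60, by = 0.01)
  v <- bump(t, 5, 0.9 * mg) + bump(t, 25, 0.8 * mg) + bump(t, 55, 0.9 * mg)
  s <- timed_stream("fz", t, matrix(v, dimnames = list(NULL, "Fz")), "Fz", "N", 100)
  ev <- event_log(c(0, 10, 50), c("stand_start", "exercise_start", "sit_start"))
  pk <- detect_cycle_peaks(s, m, events = ev)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 25, tolerance = 0.02)
})

test_that("greedy peak selection matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:25) {
    t <- seq(0, 100, by = 0.1)
    n_b <- sample(3:10, 1)
    v <- rowSums(vapply(seq_len(n_b), function(i)
      bump(t, runif(1, 5, 95), runif(1, 300, 900), runif(1, 0.5, 2)),
      numeric(length(t)))) + rnorm(length(t), sd = 10)
    m <- 80
    s <- timed_stream("fz", t, matrix(v, dimnames = list(NULL, "Fz")), "Fz", "N", 10)
    got <- detect_cycle_peaks(s, m, min_sep = 5, edge_policy = "keep")
    want_idx <- oracle_peaks(t, v, 0.5 * m * 9.81, 5)
    expect_equal(got$time, t[want_idx])
    expect_equal(got$value, v[want_idx])
    # invariants: spacing and threshold
    if (nrow(got) > 1) expect_true(all(diff(got$time) >= 5))
    expect_true(all(got$value >= 0.5 * m * 9.81))
  }
})

test_that("forces convert to percent body weight with g = 9.81", {
  expect_equal(to_bw_percent(83.3 * 9.81, 83.3), 100)
  expect_equal(to_bw_percent(0, 70), 0)
  expect_equal(to_bw_percent(400, 83.3), 48.95, tolerance = 0.005)
  expect_equal(to_bw_percent(-50, 100), -100 * 50 / (100 * 9.81))  # pull stays negative
  expect_error(to_bw_percent(10, 0), "positive")
})

test_that("co-recorded streams are sampled at peak times", {
  t <- seq(0, 10, by = 0.1)
  rec <- session_recording(
    "p", 1, 80, 16.7,
    streams = list(
      a = timed_stream("a", t, matrix(t, dimnames = list(NULL, "v")), "v", "N", 10),
      b = timed_stream("b", t, matrix(2 * t, dimnames = list(NULL, "v")), "v", "N", 10)),
    grid_rate = 10)
  at <- sample_at_peaks(rec, c(1.0, 2.35))
  expect_equal(unname(at$a[1, "v"]), 1.0)      # on-grid: exact sample
  expect_equal(unname(at$b[2, "v"]), 4.7)      # off-grid: interpolated
  expect_error(sample_at_peaks(rec, 11), "span")
})

test_that("lean angle is the arctangent of lateral over vertical", {
  ref <- c(0, 0, 1.35)
  expect_equal(lean_angle(c(0, 0, 1.35), ref), 0)
  expect_equal(lean_angle(c(1.35, 0, 1.35), ref), 45)
  expect_equal(lean_angle(c(0.135, 0, 1.35), ref), atan(0.1) * 180 / pi)
  expect_equal(round(lean_angle(c(0.135, 0, 1.35), ref), 2), 5.71)
  expect_lt(lean_angle(c(-0.2, 0, 1.35), ref), 0)   # left lean is negative
  expect_error(lean_angle(c(0, 0, 0), ref), "geometry")
})

test_that("range of motion pairs successive opposite-side cycles", {
  cyc <- data.frame(side = c("L", "R"), lean_angle = c(-6, 6))
  expect_equal(range_of_motion(cyc), 12)
  expect_equal(range_of_motion(cyc[1, ]), numeric(0))
  cyc2 <- data.frame(side = c("L", "R"), lean_angle = c(-6, 6.13))
  expect_equal(range_of_motion(cyc2), 12.13)
  # same-side repeats are skipped, trailing unpaired cycle dropped
  cyc3 <- data.frame(side = c("L", "L", "R", "L", "R", "R"),
                     lean_angle = c(-5, -6, 7, -4, 5, 6))
  expect_equal(range_of_motion(cyc3), c(13, 9))
})

test_that("ROM is invariant to a constant lateral offset", {
  xs <- c(-0.14, 0.15, -0.13, 0.16)
  ref <- c(0.02, 0, 1.35)
  ang <- function(off) vapply(xs, function(x)
    lean_angle(c(x + off, 0, 1.35), ref + c(off, 0, 0)), numeric(1))
  cyc <- function(off) data.frame(side = c("L", "R", "L", "R"),
                                  lean_angle = ang(off))
  expect_equal(range_of_motion(cyc(0)), range_of_motion(cyc(0.5)),
               tolerance = 1e-10)
})

test_that("session summaries aggregate the cycle table consistently", {
  p <- virtual_participant(83.3)
  rec <- simulate_session(p, quick_config(seed = 17, duration = 420))
  cyc <- analyze_session(rec)
  s <- summarize_session(rec, cyc, mature_after = p$habituation + 10)
  expect_equal(s$cycle_count, nrow(cyc))
  expect_true(s$defined)
  expect_equal(s$peak_bw[["mean"]], mean(cyc$peak_bw_pct))
  expect_equal(nrow(s$profile), nrow(cyc))
  expect_true(all(diff(s$profile$peak_time) > 0))
  # empty input: count zero, statistics flagged undefined
  none <- cyc[0, ]
  s0 <- summarize_session(rec, none)
  expect_equal(s0$cycle_count, 0L)
  expect_false(s0$defined)
  expect_true(is.na(s0$peak_bw[["mean"]]))
  # identical peaks: zero spread
  two <- cyc[1:2, ]
  two$peak_bw_pct <- 70
  s2 <- summarize_session(rec, two)
  expect_equal(s2$peak_bw[["sd"]], 0)
})

test_that("moving average smooths with trimmed edge windows", {
  x <- c(1, 2, 3, 4, 5)
  ma <- moving_average(x, window = 2L)
  expect_equal(length(ma), 5L)
  expect_equal(ma[3], mean(c(2, 3, 4)))
  expect_equal(moving_average(numeric(0)), numeric(0))
})
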