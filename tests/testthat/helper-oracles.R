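# Independent oracles used to cross-check package implementations.

# Brute-force peak oracle: enumerate all threshold-passing strict local
# maxima (plateaus count once, at their first sample), then iteratively
# remove the smaller member of any pair closer than min_sep until no
# violation remains.
oracle_peaks <- function(t, v, threshold, min_sep) {
  idx <- integer(0)
  i <- 2L
  n <- length(v)
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx <- idx[v[idx] >= threshold]
  repeat {
    if (length(idx) < 2) break
    dt <- outer(t[idx], t[idx], function(a, b) abs(a - b))
    viol <- which(dt < min_sep & upper.tri(dt), arr.ind = TRUE)
    if (!nrow(viol)) break
    # resolve first the violating pair containing the largest candidate
    # (keep-the-larger applied from the top down), dropping its smaller
    # member
    pair_max <- pmax(v[idx[viol[, 1L]]], v[idx[viol[, 2L]]])
    pr <- viol[which.max(pair_max), ]
    loser <- pr[which.min(v[idx[pr]])]
    idx <- idx[-loser]
  }
  sort(idx)
}

# Textbook sums-of-squares oracle for one-way repeated-measures ANOVA.
oracle_rm_anova <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_c <- k - 1L
  df_e <- (k - 1L) * (n - 1L)
  ms_c <- ss_cond / df_c
  ms_e <- ss_err / df_e
  Fv <- ms_c / ms_e
  list(F = Fv, df_factor = df_c, df_error = df_e,
       p = stats::pf(Fv, df_c, df_e, lower.tail = FALSE), ms_error = ms_e)
}

# Quadrature oracle for the studentized-range CDF P(Q <= q) with k means
# and df error degrees of freedom (df = Inf uses the single integral).
oracle_srange_cdf <- function(q, k, df = Inf) {
  inner <- function(qs) {
    stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - qs))^(k - 1),
      -9, 9, rel.tol = 1e-9)$value
  }
  if (!is.finite(df)) return(inner(q))
  # scale mixture over s = chi_df / sqrt(df)
  dens <- function(s) {
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  stats::integrate(function(s) {
    vapply(s, function(si) dens(si) * inner(q * si), numeric(1))
  }, 0, 10, rel.tol = 1e-7)$value
}

# Small random synthetic recording on a uniform grid (for IO round-trips).
random_recording <- function(seed, n = 50L, rate = 10) {
  set.seed(seed)
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  mk <- function(name, labels, units) {
    timed_stream(name, t,
                 matrix(rnorm(n * length(labels)), n, length(labels)),
                 labels, units, rate)
  }
  session_recording(
    participant_id = paste0("rt", seed), session_index = seed,
    body_mass = 70 + seed, wheelchair_mass = 16.7,
    streams = list(
      plate_left = mk("plate_left", c("Fx", "Fy", "Fz", "Mx", "My", "Mz"),
                      c("N", "N", "N", "N.m", "N.m", "N.m")),
      markers = mk("markers", c("clav_x", "clav_y", "clav_z"), "m")),
    events = event_log(c(0, 1), c("stand_start", "exercise_start")),
    grid_rate = rate)
}

# Short-session defaults used throughout the tests to keep runtimes small;
# the session structure (habituation, pre/post phases) is preserved.
quick_config <- function(seed, duration = 600, ...) {
  sim_config(seed = seed, duration = duration, ...)
}
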