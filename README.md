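# standshift

Simulation and analysis of FES-assisted weight-shift standing exercise.

People with complete spinal cord injury lose lower-limb bone mineral
density because paralyzed muscles no longer load the bones against
gravity. Instrumented standing frames address this by combining functional
electrical stimulation (FES) of the leg muscles with a side-to-side
weight-shift exercise: stimulation alternates between the legs on a cyclic
pattern (5 s ON, 3 s OFF, 1 s transitions; 30 Hz pulses, 138 mA, pulse
width 0–500 µs), the user leans over the stimulated side guided by a
skiing exergame, and force plates, instrumented arm rails and a clavicle
motion-capture marker record the biomechanics.

`standshift` implements the computational core of such a system for
researchers in rehabilitation biomechanics and neuroprosthetics:

* **stimulation** — the cyclic two-group envelope generator, pulse-train
  synthesis, schedule geometry validation (tiling/overlap/gap), continuous
  mode and discontinuity-free handover;
* **streams** — synchronized multi-rate time series, a plain-text session
  container (CSV streams + JSON sidecar), lossless round-trips;
* **sensing** — load-cell pair averaging, least-squares rail calibration
  from static-weight sweeps, 6×6 force-plate calibration matrices,
  participant weighing;
* **simulator** — a seeded virtual participant producing complete,
  physically consistent session recordings (vertical force balance at
  every sample, first-order lean dynamics, within-session habituation,
  longitudinal improvement, sensor noise);
* **exergame** — the skier-position control law, hoop schedule, scoring
  and arm-overuse warning, rendering-free;
* **analysis** — exercise-cycle segmentation from vertical ground
  reaction forces (≥ 50 % body-weight local maxima, 5 s separation,
  keep-the-larger conflict resolution), conversion to %BW
  (g = 9.81 m/s²), clavicle lean angles, range of motion over successive
  left/right cycle pairs, session summaries;
* **stats** — one-way repeated-measures ANOVA with Tukey studentized-range
  post-hoc comparisons, and first-five vs last-five session comparisons.

The core quantity throughout is a force expressed as percent body weight,
`%BW = 100·F/(m·g)`, and the core segmentation rule is: a cycle peak is a
local maximum of the raw vertical plate force of at least 50 %BW, no two
peaks closer than 5 s.

## Worked example

```r
library(standshift)

p   <- virtual_participant(body_mass = 83.3)          # default exercise profile
rec <- simulate_session(p, sim_config(seed = 1, duration = 3600))
cyc <- analyze_session(rec)
s   <- summarize_session(rec, cyc, mature_after = p$habituation + 10)

s$cycle_count
#> [1] 687
round(s$peak_bw_mature, 2)
#>  mean    sd
#> 75.22  0.26
round(s$arm_bw, 2)
#> mean   sd
#> 7.57 0.87
round(mean(range_of_motion(cyc)), 2)
#> [1] 11.87
```

A 60-minute simulated session yields 687 countable exercise cycles; after
the ~5-minute habituation ramp the supporting leg carries about 75 %BW at
each cycle peak, the arms about 7.6 %BW, and successive left/right lean
pairs span about 12° of trunk motion. Session containers written with
`write_session()` are plain directories of CSV stream tables plus a
`session.json` sidecar.

Longitudinal series and group statistics:

```r
series <- simulate_longitudinal(p, 12, sim_config(seed = 1), master_seed = 7)
means  <- sapply(series, function(r) {
  k <- analyze_session(r)
  mean(k$peak_bw_pct[k$peak_time > p$habituation + 10])
})
# combine rows from several participants, then:
# compare_periods(rbind(...), n_group = 5)
```

A thin command-line front end is installed at `exec/standshift`
(subcommands `simulate`, `simulate-longitudinal`, `analyze`, `stats`).

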