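# fixpupil

Event-locked analysis of fixational saccades and pupil dynamics around
self-paced motor actions.

Fixational saccades (microsaccades) are inhibited over the second or so
before a spontaneous limb movement and rebound just after it, while the
pupil dilates ahead of the movement and re-constricts afterwards. The two
modulations covary across individual movements, which bears on whether
they share a neural origin. `fixpupil` is an R implementation of the full
measurement pipeline for this class of question on binocular 1000-Hz
eye-tracking recordings, for oculomotor and pupillometry researchers:

* **Preprocessing** — binocularly verified blink detection, median-anchored
  linear blink interpolation, and the pupil *change-rate* signal: the first
  difference of the mean-of-eyes pupil diameter (mm/s), zero-phase low-pass
  filtered (3rd-order Butterworth, 25 Hz).
* **Saccade detection** — a binocular velocity-threshold detector: 5-point
  velocity `v_n = (x_{n+2}+x_{n+1}-x_{n-1}-x_{n-2})/(6 dt)`, per-run robust
  thresholds `eta = lambda * sigma` with
  `sigma^2 = median(v^2) - median(v)^2`, candidates where
  `(v_x/eta_x)^2 + (v_y/eta_y)^2 > 1`, binocular merging, and the 8–200-ms
  duration and 10-ms blink-margin rules.
* **Event-locked rate curves** — saccades/s per 25-ms bin from −2.5 to +3 s
  around each motor event, `rate_b = count_b / (0.025 * n_events_b)`, with
  overlapping peri-event spans removed from *both* neighboring windows, a
  250-ms boxcar smoother, and per-event suppression/rebound metrics.
* **Pupil deconvolution** — a staggered (Toeplitz-style) FIR design at
  1/30-s resolution regressing the change-rate signal on press, run-start
  and optional oculomotor nuisance events, solved by ridge regression with
  exact leave-one-out penalty selection; kernels integrate to size curves
  by cumulative Riemann sum.
* **Cluster statistics** — pointwise one-sample t-tests against baseline,
  clusters of consecutive same-signed significant timepoints, cluster mass
  = summed t, and a 1000-iteration baseline-mirroring (sign-flip) Monte
  Carlo null of extreme masses.
* **Per-event covariation** — per participant, standardized (z-scored,
  no-intercept) OLS of saccade-rate modulation on pupil modulation, tonic
  pupil size (30-s boxcar) and the flanking inter-press intervals, then a
  group-level t-test per predictor.
* **Latencies** — extremum-to-extremum lags between the rate curve and the
  pupil kernel, and the pupil light reflex latency from luminance-step
  kernels.
* **Synthetic sessions** — `render_session()` generates ground-truth data:
  truncated-exponential press intervals (scale 4.6 s, 3–8 s), saccades as
  an inhomogeneous Poisson process with press-locked suppression/rebound,
  minimum-jerk gaze displacements with realistic kinematics, linearly
  superposing pupil kernels, per-press shared amplitude factors coupling
  the two signals, and blink artifacts.

See the methods vignette (`vignettes/fixpupil-methods.Rmd`) for the models,
assumptions, parameter defaults and validation-study design.

## Worked example

Simulate a 10-participant cohort and run the full pipeline (about a minute
on a laptop):

```r
library(fixpupil)

bundle <- run_pipeline(pipeline_config(
  seed = 3,
  simulate = list(n_participants = 10),
  stats = list(n_iter = 500)))

subset(bundle$rate_clusters$clusters, mc_p < 0.05)
#>     start     end sign      mass  mc_p
#> 3 -0.6875 -0.0625   -1 -114.0215 0.016
#> 4  0.1625  1.0125    1  144.8176 0.006
```

The cluster test flags a significant drop in saccade rate spanning roughly
the 0.7 s leading up to the press (negative sign, Monte Carlo p = 0.016 at
500 iterations) and a significant rebound above baseline from about +0.2
to +1.0 s — the injected suppression/rebound pattern, recovered from raw
simulated gaze traces.

```r
bundle$group_test[, c("predictor", "t", "df", "p", "median", "prop_positive")]
#>       predictor          t df           p       median prop_positive
#> 1     pupil_mod  3.8106878  9 0.004148744  0.246719994           0.9
#> 2   tonic_pupil  0.2450222  9 0.811934623  0.009114464           0.6
#> 3  interval_pre -0.5387967  9 0.603097036 -0.013520426           0.4
#> 4 interval_post  1.4831033  9 0.172196199  0.086239979           0.8
```

Across presses, the standardized pupil-modulation coefficient is positive
in 9 of 10 simulated participants (group t(9) = 3.81, p = 0.004): presses
with stronger pupil modulation also show stronger saccade-rate modulation,
while the interval and tonic-pupil confounds stay non-significant — the
generator's per-press coupling, recovered by the covariation stage.

```r
sprintf("pre lag: %.0f ms, post lag: %.0f ms",
        bundle$lags$pre_lag_ms, bundle$lags$post_lag_ms)
#> [1] "pre lag: 38 ms, post lag: 596 ms"
```

The lag report gives the latency from the rate minimum to the pupil
change-rate peak and from the rate peak to the pupil change-rate minimum,
both quantized by the 25-ms and 1/30-s analysis grids.

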