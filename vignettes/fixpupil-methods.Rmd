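---
title: "Event-locked fixational-saccade and pupil analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked fixational-saccade and pupil analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixpupil)
```

## The scientific problem

Fixational saccades (microsaccades) are small ballistic eye movements made
during intended fixation. Their rate is modulated around self-paced limb
movements: it declines steadily over roughly the second before a button or
pedal press and rebounds briefly above baseline just after. The pupil shows
a matching pattern of opposite sign — gradual dilation before the press,
rapid re-constriction after — and the amplitudes of the two modulations
covary across individual presses, which is evidence for a shared neural
drive rather than a chain of visual causation. `fixpupil` implements the
complete measurement pipeline for this kind of question on binocular
1000-Hz eye-tracking data, plus a synthetic session generator with full
ground truth, so that every stage can be validated by parameter recovery.

## Signal preprocessing

Blinks appear in video-based tracker output as a rapid collapse of the
registered pupil, a gap of absent samples, and a rapid recovery, roughly
simultaneous in the two eyes. `detect_blinks()` flags, per eye and run,
maximal spans where |pupil change rate| exceeds `change_threshold`
(default 25 mm/s — far above any physiological dilation rate) or the signal
is absent, bridges gaps shorter than `merge_gap` (50 ms), and accepts a
candidate as a blink only if the two eyes' candidates overlap. Signal
absence that fails the binocularity check becomes a missing-data mask
instead. The thresholds are configuration-exposed because they describe the
artifact, not the biology.

Pupil diameters (already in mm) are averaged across eyes *before*
differentiation, falling back to the valid eye during monocular dropouts.
Each blink, padded by 20 ms, is replaced by the straight line joining the
median pupil size in a 50-ms window just before the padded interval to the
median just after (medians anchored at their window centers, which makes
the interpolation exact on locally linear trends); blinks abutting a run
edge are left missing rather than extrapolated. The first difference of
the interpolated trace, scaled to mm/s, is low-pass filtered with a
third-order Butterworth filter at a 25-Hz critical frequency. Filtering is
zero-phase (forward–backward): the latency analyses below depend on
event-locked timing, and a causal pass would delay every feature by the
filter's group delay. Filtering never crosses run boundaries.

## Saccade detection

Detection is a binocular velocity-threshold algorithm. Velocities use the
5-point moving-window derivative
`v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`, which is exact on
linear motion. Per run and component, the threshold is `lambda * sigma`
with the robust scale `sigma^2 = median(v^2) - median(v)^2`, so the
saccades themselves barely influence it; `lambda = 6` by default, the
conservative choice in the microsaccade literature (note the median-based
scale converges to ~0.67 SD for Gaussian noise, so the effective Gaussian
threshold is ~4 SD). Candidates are maximal spans where
`(vx/eta_x)^2 + (vy/eta_y)^2 > 1` lasting at least 6 ms. Candidates from
the two eyes are pooled; spans separated by 5 ms or less merge into one
candidate, labeled binocular iff both eyes contributed. Retained saccades
must be binocular, last 8–200 ms, and lie more than 10 ms from any blink
(video trackers register artifactual gaze excursions around blinks). Each
saccade is timestamped at the midpoint of start and end; amplitude and
direction come from the displacement of the mean-of-eyes gaze between the
first and last sample of the span — the mean is a documented choice (the
natural symmetric estimate), since either eye alone would be equally
defensible.

## Event-locked saccade rate

Raw presses less than 300 ms apart collapse, by chained comparison to the
previous raw press, into a single motor event at the first press (pedals
can bounce while held). Around each motor event a window from −2.5 s to
+3 s is tiled with 25-ms bins; each saccade contributes, via its midpoint
timestamp, to exactly one bin of exactly one event. When two events'
windows overlap in absolute time, the shared span is removed from **both**
windows — from counts and denominators alike — so no saccade can be
attributed to two events and no ambiguous span contributes at all; bins
extending beyond the run are likewise excluded. The rate in a bin is the
summed count divided by (0.025 s × number of validly contributing events).
Curves are smoothed with a 250-ms sliding boxcar implemented as the 10-bin
window `b-5 .. b+4` (exact 250-ms width on a 25-ms grid; bins with zero
denominator are excluded; edges use available bins). The baseline is the
time-weighted rate over the first 500 ms and last 1000 ms of the window.

Two per-event metrics quantify modulation for individual presses: the rate
in the rebound window (+0.2 to +1.2 s) minus the rate in the suppression
window (−0.8 to 0 s), each count divided by its own window's width (the
windows deliberately have different lengths, so a common divisor would be
wrong), and analogously for the pupil below. Events with a neighbor closer
than 2.5 s are flagged invalid for these metrics.

## Pupil deconvolution

Pupil responses are slow (seconds), so responses to successive presses
overlap heavily at ~5-s inter-press intervals, and plain event-locked
averaging is biased by neighbors. Under approximate linear superposition a
finite-impulse-response model separates them: the pupil *change-rate*
signal, block-averaged into 1/30-s frames per run, is regressed on a
staggered design in which each event type contributes one indicator column
per 1/30-s offset within its window (presses: −2 to +5.5 s; run starts, a
nuisance whose onset transient would otherwise contaminate press kernels:
0 to 5.5 s; optional blink and saccade nuisances: 0–4 s and 0–2 s;
luminance steps: 0–4 s). Columns hold a 1 at the frame containing the
shifted event time; out-of-run placements are dropped. Missing frames are
dropped row-wise — blink interpolation has already handled the gaps worth
repairing.

The model is solved by ridge regression with the penalty selected from
{0.1, 1, 10} by exact leave-one-out cross-validation computed from the
SVD (the grid mirrors common solver defaults; at these problem sizes the
solution is insensitive to it). Both sides are centered, which makes a
zero response map to exactly zero kernels. The beta weights of a column
set form that event type's kernel (mm/s at 1/30-s offsets); a cumulative
Riemann sum times 1/30 s converts a kernel to pupil size relative to the
window start. Leave-one-out folds ignore run boundaries — frames are the
exchangeable unit here, and the documented default.

## Cluster-mass sign-flip statistics

To find spans where an event-locked signal deviates from baseline across
participants without a per-bin multiplicity problem: at each timepoint a
two-tailed one-sample t-test compares `curve - own baseline` to zero;
maximal runs of consecutive timepoints with p < 0.05 and a common effect
sign form clusters with mass = summed t-values. The null distribution
comes from 1000 Monte Carlo iterations in which each participant's curve
is independently mirrored in its baseline (`2*baseline - curve`) with
probability 1/2 — an involution, so the null preserves each participant's
variance exactly — and the maximal |mass| is stored. A cluster's Monte
Carlo p is the proportion of null values *strictly* exceeding its |mass|
(the strict inequality is the documented reading of "more extreme"; both
signs are pooled via the absolute value). Zero-variance timepoints are
assigned t = 0, p = 1 so that degenerate synthetic inputs cannot crash the
procedure. For saccade-rate input the per-participant baseline is the
first-500-ms/last-1000-ms rate; for pupil change-rate kernels the baseline
is 0 mm/s.

## Per-event covariation

For each participant, every motor event that is isolated (no neighbor
within 2.5 s), not the first or last of its run (its flanking intervals
would be undefined), and complete in all columns contributes one row:
saccade-rate modulation (response), pupil modulation, tonic pupil size at
the event (30-s centered boxcar of the preprocessed pupil trace, run-
restricted, missing data ignored; if the event's sample is missing, the
nearest non-missing sample within 1 s is used), and the intervals to the
previous and next event. All five columns are z-scored with the
participant's own mean and SD (`ddof = 1`; the paper-level convention is
unstated, and this is R's default) and ordinary least squares is fit
without an intercept — z-scoring forces it to zero, and omitting it keeps
the coefficients exactly the standardized betas. Participants with fewer
than 10 usable events are excluded. Each predictor's across-participant
coefficient distribution is tested against zero with a two-tailed
one-sample t-test; medians, interquartile ranges and the proportion of
positive coefficients are reported alongside. The interval predictors are
there to absorb spacing confounds: any amplitude structure that is a
function of the inter-press interval is captured by them, so a pupil
coefficient survives only if the saccade–pupil association holds at fixed
spacing.

## Latency measures

Lags are measured on across-participant average curves, as extremum-to-
extremum delays: the pre-event lag runs from the saccade-rate minimum
(search window −1 to +0.2 s) to the pupil change-rate peak (−1 to +0.5 s);
the post-event lag from the first rate peak (0 to +1.2 s) to the first
pupil change-rate minimum (0 to +2 s). Search windows bracket the features
and are configuration-exposed, since only qualitative descriptions pin
them down. Ties break toward the earliest offset, and extrema landing on a
window boundary raise a truncation warning. The pupil light reflex latency
is the offset of the most negative change rate (most rapid constriction)
in the luminance-increment kernel within 1.5 s of light onset; a kernel
with no interior minimum is an error. All latencies are quantized by their
grids (25 ms for rate, 1/30 s for pupil), and reported as such.

## The synthetic generator

`render_session()` produces sessions whose statistical structure matches
the pipeline's assumptions, with complete ground truth:

* **Presses** arrive at truncated-exponential intervals (scale 4.6 s,
  range 3–8 s; mean ≈ 5.06 s), in runs of 45 s.
* **Saccade times** follow an inhomogeneous Poisson process: baseline
  0.89 /s multiplied, per press, by a linear ramp down to
  `1 - suppression_depth` over the second before the press and a boxcar at
  `1 + rebound_gain` over +0.2 to +1.2 s (defaults 0.5 and 0.3, matching
  the qualitative strength of the published group curves). Overlapping
  event modulations multiply, clipped at zero. Simulation is by thinning
  against the tabulated intensity, followed by a 25-ms dead time —
  ballistic movements closer than that are physically unresolvable and
  would be fused by the detector's merge rule. `injected_rate_curve()`
  declares the resulting ground truth exactly: the intensity averaged over
  the amplitude distribution, dead-time corrected by
  `lambda/(1 + lambda*d)` (exact for a renewal dead time, quasi-static for
  our slowly varying intensities), and convolved with the half-duration
  distribution because the analysis timestamps saccades at their
  midpoints.
* **Kinematics**: amplitudes are log-normal (median 21.3 arcmin,
  log-SD 0.58, truncated to 8–120 arcmin), durations log-normal (median
  19 ms, log-SD 0.42, truncated to 10–60 ms), directions normal about
  horizontal with 8° SD (≈78.5% within 10° of horizontal), with a
  corrective tendency toward screen center. The truncations acknowledge
  that a relative-threshold detector cannot resolve events below the
  tracker noise floor. Each saccade is rendered as a minimum-jerk
  displacement — smooth, velocity-peaked mid-flight.
* **Pupil**: change rate = superposition of a press-locked kernel (Gaussian
  dilation lobe peaking 0.2 s before the press at 0.12 mm/s, balanced
  constriction lobe at +0.9 s so the kernel integrates to zero), scaled per
  press by a shared amplitude factor; the trace is the baseline plus the
  running integral plus white noise per eye. Luminance-step sessions use a
  deep constriction kernel (−1.2 mm/s at 400 ms — light reflexes are the
  largest phasic pupil responses) for increments and a mirrored, scaled
  kernel for decrements. A slow tonic drift (two incommensurate sinusoids,
  periods 23 s and 41 s, random phases, default amplitude 0.1 mm) gives
  the tonic-pupil predictor genuine slow-timescale variation to measure —
  without it the predictor is nearly degenerate and its standardized
  betas are ill-conditioned.
* **Coupling**: one log-normal factor per press (log-SD 0.6, capped at 1.9
  and rescaled to unit mean so the suppressed rate never clips) scales both
  the press's rate modulation depth and its pupil kernel. This creates the
  across-press association the covariation stage is built to detect. The
  log-normal is a modeling stand-in — the real per-event amplitude
  distribution is unknown; only the covariation itself is an empirical
  target. An alternative `interval` mode makes the amplitude a linear
  function of the preceding interval, a pure confound that the interval
  predictors must absorb.
* **Artifacts**: blinks (default 4/min) as a 40-ms linear collapse, 100-ms
  binocular gap, 40-ms recovery, placed away from run boundaries; white
  positional noise (0.002° per eye) standing in for the tracker noise
  floor.

What the generator does **not** emulate: ocular drift and tremor (gaze
noise is white), structured hippus beyond the smooth tonic drift,
main-sequence amplitude–duration coupling, luminance
dependence of the motor-locked pupil response, and any refractoriness of
pressing beyond the truncated-interval floor. Passing recovery tests
therefore shows the pipeline is correct under its own assumptions — not
that those assumptions exhaust real data.

## Validation studies and problem sizes

The `validate_*()` family re-runs the pipeline on fresh simulations and
measures recovery; the shipped checks use these sizes (chosen to balance
statistical resolution against desk-scale runtimes):

* detector recovery: 4 artifact-free sessions (~1100 injected saccades);
* rate recovery: 3 replicate cohorts of 30 participants × ~58 events;
  the per-cohort coverage proportion (fraction of bins where the mean
  smoothed curve sits within 2 SE of the injected curve) is itself random
  with sd of several percentage points — participants' Poisson totals move
  all bins coherently — so the replicate mean is reported, with the
  cluster flags required in every replicate;
* deconvolution recovery: 10-run sessions with 12-s spacing (no overlap)
  and with the task's own 3–8-s spacing (heavy overlap), compared against
  naive event-locked averaging;
* cluster calibration: 200 null datasets of 20 participants × 60 events,
  200 Monte Carlo iterations each;
* covariation: 30 participants with coupling on; 40 replicate suites of
  12 participants × 4 runs with coupling off, requiring each predictor to
  stay non-significant at α = 0.01 in at least 95% of suites (40 suites
  give the fraction a granularity of 2.5%, so up to two chance hits per
  predictor are tolerated, in line with the 1% nominal rate);
* latency: 24 participants with a sharpened modulation (suppression 0.8,
  rebound gain 1.2 over +0.2 to +0.45 s) — with the default boxcar rebound
  the smoothed rate peak is a plateau whose location is not identified, so
  the latency construction narrows the rebound to the smoothing width;
  pupil noise is off and the pupil kernel is time-shifted so the analytic
  extremum lag is 300 ms; the light reflex uses 10 participants × 5 runs.

## Numerical and degenerate-input conventions

Zero-variance timepoints: t = 0, p = 1. A velocity trace with zero robust
variance yields no candidates and a warning (the threshold is undefined).
Ties at extrema break earliest. Ridge columns for event types with no
occurrences stay exactly zero and do not perturb other kernels. Session
files store doubles losslessly (`%.17g`) with `NA` as the missing token,
so write–read–write cycles are byte-identical. All simulation and Monte
Carlo randomness is controlled by explicit integer seeds; identical
configuration and seed reproduce bit-identical sessions and results.

## Known limitations

The dead-time correction is quasi-static and first-order exact only for
intensities varying slowly relative to 25 ms (true here). The FIR design
quantizes event times to 1/30-s frames; sub-frame timing is recovered only
on average. The two-stage covariation procedure (per-participant OLS, then
a group t-test) follows the published analysis deliberately; a mixed-model
alternative is out of scope. Latency estimates inherit their grids'
resolution and are only as well-defined as the curves' extrema are sharp.
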