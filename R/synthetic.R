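#' Simulation configuration for synthetic eye-tracking sessions
#'
#' Bundles every parameter of the synthetic session generator. The defaults
#' describe a self-paced button-press task recorded binocularly at 1000 Hz:
#' presses arrive at truncated-exponential intervals (scale 4.6 s, truncated
#' to 3--8 s, i.e. a mean interval just over 5 s), fixational saccades follow
#' an inhomogeneous Poisson process with baseline rate 0.89 /s that is
#' suppressed over the second before each press and rebounds briefly after,
#' and the pupil change rate superposes an event-locked
#' dilation-then-constriction kernel across presses. A log-normal per-event
#' amplitude factor (mean 1) scales both the saccade-rate modulation and the
#' pupil kernel of each press, creating the across-press coupling the
#' covariation analysis is designed to recover.
#'
#' @param sampling_rate samples per second (Hz).
#' @param run_duration duration of one run in seconds.
#' @param n_runs number of runs in the session.
#' @param interval_scale,interval_lo,interval_hi scale and truncation bounds
#'   (s) of the exponential inter-press interval distribution.
#' @param baseline_saccade_rate baseline fixational saccade rate (saccades/s).
#' @param suppression_depth fractional rate suppression reached at the press
#'   (0 = none, 1 = complete silence).
#' @param rebound_gain fractional rate elevation during the rebound window.
#' @param ramp_window time window (s, relative to the press) over which the
#'   rate ramps linearly down to `1 - suppression_depth`.
#' @param rebound_window time window (s) of the boxcar rebound at
#'   `1 + rebound_gain`.
#' @param pupil_baseline baseline pupil diameter (mm).
#' @param pupil_kernel parameters of the press-locked pupil change-rate
#'   kernel (mm/s): a positive Gaussian dilation lobe (`dilate_peak`,
#'   `dilate_sd`, `dilate_amp`) and a negative constriction lobe
#'   (`constrict_peak`, `constrict_sd`) whose amplitude is set so the kernel
#'   integrates to zero (the pupil returns to baseline).
#' @param run_onset_amp amplitude (mm/s) of a dilation transient locked to
#'   run starts (a nuisance response the deconvolution must absorb); 0
#'   disables it.
#' @param plr_kernel parameters of the luminance-step pupil kernels used for
#'   `task = "plr"`: a deep constriction lobe for luminance increments
#'   (`constrict_amp`, `constrict_peak`, `constrict_sd`) plus a slow recovery
#'   lobe; decrements use the mirrored kernel scaled by `decrement_scale`.
#' @param coupling_sd standard deviation (log scale) of the log-normal
#'   per-event amplitude factor; 0 disables coupling.
#' @param coupling_mode `"shared"` for the log-normal shared factor,
#'   `"interval"` for an amplitude that is a linear function of the preceding
#'   inter-press interval (a confound with no residual saccade--pupil
#'   coupling), `"none"` for constant unit amplitude.
#' @param amp_median_arcmin,amp_sigma,amp_range log-normal saccade amplitude
#'   distribution (median in arcmin, log-sd) and truncation range.
#' @param dur_median_ms,dur_sigma,dur_range log-normal saccade duration
#'   distribution (median in ms, log-sd) and truncation range.
#' @param dir_sd_deg SD (deg) of the saccade direction about the horizontal
#'   axis; with the default 8 deg about 78.5% of saccades fall within 10 deg
#'   of horizontal.
#' @param tonic_drift_mm amplitude (mm) of the slow tonic pupil drift (two
#'   incommensurate slow sinusoids with random phases, periods 23 s and
#'   41 s); emulates the slow-timescale pupil variation the tonic-pupil
#'   predictor measures. 0 disables it.
#' @param noise_sd_gaze per-eye white positional noise SD (deg).
#' @param noise_sd_pupil per-eye white pupil noise SD (mm).
#' @param blink_rate blink rate (per minute); 0 disables blinks.
#' @param effector effector label attached to press events.
#' @param seed integer seed; the whole session is deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [render_session()], [sample_intervals()], [simulate_saccade_times()]
#' @export
sim_config <- function(sampling_rate = 1000, run_duration = 45, n_runs = 7,
                       interval_scale = 4.6, interval_lo = 3, interval_hi = 8,
                       baseline_saccade_rate = 0.89,
                       suppression_depth = 0.5, rebound_gain = 0.3,
                       ramp_window = c(-1, 0), rebound_window = c(0.2, 1.2),
                       pupil_baseline = 4.5,
                       pupil_kernel = list(dilate_peak = -0.2, dilate_sd = 0.35,
                                           dilate_amp = 0.12,
                                           constrict_peak = 0.9, constrict_sd = 0.45),
                       run_onset_amp = 0.08,
                       plr_kernel = list(constrict_peak = 0.4, constrict_sd = 0.12,
                                         constrict_amp = -1.2,
                                         recover_peak = 1.0, recover_sd = 0.35,
                                         recover_amp = 0.25,
                                         decrement_scale = 0.8),
                       coupling_sd = 0.6, coupling_mode = c("shared", "interval", "none"),
                       amp_median_arcmin = 21.3, amp_sigma = 0.58, amp_range = c(8, 120),
                       dur_median_ms = 19, dur_sigma = 0.42, dur_range = c(10, 60),
                       dir_sd_deg = 8, tonic_drift_mm = 0.1,
                       noise_sd_gaze = 0.002, noise_sd_pupil = 0.002,
                       blink_rate = 4, effector = "hand", seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(sampling_rate = sampling_rate, run_duration = run_duration,
              n_runs = n_runs, interval_scale = interval_scale,
              interval_lo = interval_lo, interval_hi = interval_hi,
              baseline_saccade_rate = baseline_saccade_rate,
              suppression_depth = suppression_depth, rebound_gain = rebound_gain,
              ramp_window = ramp_window, rebound_window = rebound_window,
              pupil_baseline = pupil_baseline, pupil_kernel = pupil_kernel,
              run_onset_amp = run_onset_amp, plr_kernel = plr_kernel,
              coupling_sd = coupling_sd, coupling_mode = coupling_mode,
              amp_median_arcmin = amp_median_arcmin, amp_sigma = amp_sigma,
              amp_range = amp_range, dur_median_ms = dur_median_ms,
              dur_sigma = dur_sigma, dur_range = dur_range,
              dir_sd_deg = dir_sd_deg, tonic_drift_mm = tonic_drift_mm,
              noise_sd_gaze = noise_sd_gaze,
              noise_sd_pupil = noise_sd_pupil, blink_rate = blink_rate,
              effector = effector, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0, cfg$run_duration > 0, cfg$n_runs >= 0)
  if (cfg$interval_lo >= cfg$interval_hi)
    stop("invalid interval range: interval_lo must be < interval_hi")
  if (cfg$interval_scale <= 0) stop("interval_scale must be > 0")
  if (cfg$baseline_saccade_rate < 0) stop("rates must be >= 0")
  if (cfg$suppression_depth < 0 || cfg$suppression_depth > 1)
    stop("suppression_depth must lie in [0, 1]")
  if (cfg$rebound_gain < 0) stop("rebound_gain must be >= 0")
  if (cfg$blink_rate < 0) stop("blink_rate must be >= 0")
  if (cfg$coupling_sd < 0) stop("coupling_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_runs, "runs x", x$run_duration, "s at",
      x$sampling_rate, "Hz;", "baseline", x$baseline_saccade_rate,
      "saccades/s; suppression", x$suppression_depth, "/ rebound",
      x$rebound_gain, "; coupling", x$coupling_mode,
      sprintf("(sd %.2f);", x$coupling_sd), "seed", x$seed, "\n")
  invisible(x)
}

#' Sample truncated-exponential inter-event intervals
#'
#' Draws intervals from an exponential distribution conditioned on a range,
#' by inverse-CDF sampling. With the default task parameters (scale 4.6 s,
#' range 3--8 s) the mean interval is approximately 5.057 s.
#'
#' @param scale exponential scale parameter (s).
#' @param lo,hi truncation bounds (s), `lo < hi`.
#' @param n number of intervals.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` intervals, each in `[lo, hi]`.
#' @export
sample_intervals <- function(scale, lo, hi, n, seed = NULL) {
  if (lo >= hi) stop("invalid interval range: lo must be < hi")
  stopifnot(scale > 0, n >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::runif(n)
  w <- hi - lo
  lo - scale * log1p(-u * (1 - exp(-w / scale)))
}

#' Mean and CDF of the truncated exponential interval distribution
#'
#' Closed forms used as oracles: the conditional mean
#' `lo + scale - w * exp(-w/scale) / (1 - exp(-w/scale))` with `w = hi - lo`,
#' and the conditional CDF.
#'
#' @inheritParams sample_intervals
#' @return `truncexp_mean()` returns the mean (s); `truncexp_cdf()` a
#'   function of `x`.
#' @export
truncexp_mean <- function(scale, lo, hi) {
  w <- hi - lo
  lo + scale - w * exp(-w / scale) / (1 - exp(-w / scale))
}

#' @rdname truncexp_mean
#' @export
truncexp_cdf <- function(scale, lo, hi) {
  z <- 1 - exp(-(hi - lo) / scale)
  function(x) pmin(1, pmax(0, (1 - exp(-(x - lo) / scale)) / z))
}

#' Event-locked saccade-rate modulation profile
#'
#' Returns the multiplicative modulation `m(tau)` applied to the baseline
#' saccade rate at offset `tau` (s) from a motor event: a linear ramp from 1
#' down to `1 - suppression_depth` over `ramp_window`, a boxcar at
#' `1 + rebound_gain` over `rebound_window`, and 1 elsewhere.
#'
#' @param tau numeric vector of offsets (s).
#' @param config a [sim_config()].
#' @return Numeric vector of multipliers, same length as `tau`.
#' @export
rate_modulation <- function(tau, config) {
  m <- rep(1, length(tau))
  rw <- config$ramp_window
  in_ramp <- tau >= rw[1] & tau < rw[2]
  frac <- (tau[in_ramp] - rw[1]) / (rw[2] - rw[1])
  m[in_ramp] <- 1 - config$suppression_depth * frac
  bw <- config$rebound_window
  m[tau >= bw[1] & tau < bw[2]] <- 1 + config$rebound_gain
  m
}

#' Press-locked pupil change-rate kernel
#'
#' Evaluates the generator's pupil change-rate kernel (mm/s) at offsets `tau`
#' (s) from a press: a Gaussian dilation lobe followed by a Gaussian
#' constriction lobe whose amplitude is fixed so the kernel integrates to
#' zero.
#'
#' @inheritParams rate_modulation
#' @return Numeric vector of change rates (mm/s).
#' @export
pupil_kernel_fun <- function(tau, config) {
  k <- config$pupil_kernel
  con_amp <- -k$dilate_amp * k$dilate_sd / k$constrict_sd
  k$dilate_amp * exp(-(tau - k$dilate_peak)^2 / (2 * k$dilate_sd^2)) +
    con_amp * exp(-(tau - k$constrict_peak)^2 / (2 * k$constrict_sd^2))
}

#' @rdname pupil_kernel_fun
#' @param type `"lum_increment"` (light reflex: constriction) or
#'   `"lum_decrement"` (dark reflex: mirrored, scaled dilation).
#' @export
plr_kernel_fun <- function(tau, config, type = c("lum_increment", "lum_decrement")) {
  type <- match.arg(type)
  k <- config$plr_kernel
  v <- k$constrict_amp * exp(-(tau - k$constrict_peak)^2 / (2 * k$constrict_sd^2)) +
    k$recover_amp * exp(-(tau - k$recover_peak)^2 / (2 * k$recover_sd^2))
  if (type == "lum_decrement") v <- -k$decrement_scale * v
  v
}

run_onset_kernel_fun <- function(tau, config) {
  config$run_onset_amp * exp(-(tau - 1)^2 / (2 * 0.8^2))
}

#' Simulate saccade times from an inhomogeneous Poisson process
#'
#' Realizes saccade times on `[0, run_duration)` for an intensity equal to
#' `baseline_rate` multiplied by the product, over nearby events, of the
#' per-event modulation `1 + a_i * (profile(tau) - 1)`. The product is
#' clipped at zero. Simulation is by thinning against the tabulated
#' piecewise-constant intensity on a `dt` grid, so the tabulated intensity
#' is the exact generative intensity (the time-rescaling theorem applies
#' exactly to its running integral).
#'
#' @param event_times event times (s) within the run.
#' @param run_duration run duration (s).
#' @param baseline_rate baseline intensity (saccades/s), must be >= 0.
#' @param profile vectorized function of the offset (s) returning the
#'   multiplicative modulation; defaults to no modulation.
#' @param event_amplitude per-event amplitude factors scaling the modulation
#'   depth (one per event).
#' @param refractory_s dead time: minimum separation between consecutive
#'   saccade onsets (arrivals closer than this to the last kept saccade are
#'   dropped). The kept process realizes the rate
#'   `lambda(t) / (1 + lambda(t) * refractory_s)` for slowly varying
#'   intensities, which [injected_rate_curve()] accounts for exactly.
#' @param dt tabulation step (s).
#' @param seed optional integer seed.
#' @return Sorted numeric vector of saccade times (s).
#' @export
simulate_saccade_times <- function(event_times, run_duration, baseline_rate,
                                   profile = NULL,
                                   event_amplitude = rep(1, length(event_times)),
                                   refractory_s = 0.025, dt = 0.001, seed = NULL) {
  if (baseline_rate < 0) stop("negative intensity: baseline_rate must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lam <- saccade_intensity(event_times, run_duration, baseline_rate,
                           profile, event_amplitude, dt)
  if (any(!is.finite(lam))) stop("non-finite intensity from modulation profile")
  lam_max <- max(lam)
  if (lam_max <= 0) return(numeric(0))
  n_prop <- stats::rpois(1, lam_max * run_duration)
  if (n_prop == 0) return(numeric(0))
  tp <- sort(stats::runif(n_prop, 0, run_duration))
  acc <- stats::runif(n_prop) < lam[pmin(length(lam), floor(tp / dt) + 1L)] / lam_max
  ts <- tp[acc]
  if (refractory_s > 0 && length(ts) > 1) {
    keep <- logical(length(ts))
    keep[1] <- TRUE
    last <- ts[1]
    for (i in seq_along(ts)[-1]) {
      if (ts[i] - last >= refractory_s) {
        keep[i] <- TRUE
        last <- ts[i]
      }
    }
    ts <- ts[keep]
  }
  ts
}

# Tabulate the generative intensity on a dt grid (left-edge convention).
saccade_intensity <- function(event_times, run_duration, baseline_rate,
                              profile = NULL, event_amplitude = rep(1, length(event_times)),
                              dt = 0.001, support = 3.5) {
  tg <- seq(0, run_duration - dt, by = dt)
  mod <- rep(1, length(tg))
  if (!is.null(profile) && length(event_times)) {
    stopifnot(length(event_amplitude) == length(event_times))
    for (i in seq_along(event_times)) {
      idx <- which(tg >= event_times[i] - support & tg <= event_times[i] + support)
      if (!length(idx)) next
      m <- 1 + event_amplitude[i] * (profile(tg[idx] - event_times[i]) - 1)
      mod[idx] <- mod[idx] * m
    }
  }
  baseline_rate * pmax(mod, 0)
}

AMP_CAP <- 1.9

capped_lnorm_mean <- function(sdlog, cap = AMP_CAP) {
  # E[min(a, cap)] for a ~ lognormal with unit mean (meanlog = -sdlog^2/2)
  mu <- -sdlog^2 / 2
  stats::pnorm((log(cap) - mu - sdlog^2) / sdlog) +
    cap * (1 - stats::pnorm((log(cap) - mu) / sdlog))
}

# quantile grid of the capped, mean-one amplitude distribution
amplitude_quadrature <- function(config, n = 101) {
  if (config$coupling_mode != "shared" || config$coupling_sd == 0) return(1)
  p <- (seq_len(n) - 0.5) / n
  pmin(stats::qlnorm(p, -config$coupling_sd^2 / 2, config$coupling_sd), AMP_CAP) /
    capped_lnorm_mean(config$coupling_sd)
}

minjerk_steps <- function(n) {
  # displacement increments of a minimum-jerk profile across n samples
  tau <- seq(0, 1, length.out = n + 1)
  diff(10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

draw_truncated_lnorm <- function(n, meanlog, sdlog, range) {
  plo <- stats::plnorm(range[1], meanlog, sdlog)
  phi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Render a full synthetic session
#'
#' Generates a complete binocular session with ground truth: run-structured
#' event logs, per-press-modulated fixational saccades rendered as
#' minimum-jerk gaze displacements, a pupil trace equal to baseline plus the
#' time-integral of the superposed per-event change-rate kernels (scaled by
#' the per-event amplitude factor), independent per-eye white noise, and
#' (optionally) blinks. With `task = "plr"` the session instead contains
#' luminance increment/decrement events driving the light- and dark-reflex
#' kernels, with saccades at constant baseline rate.
#'
#' @param config a [sim_config()].
#' @param task `"motor"` (self-paced presses) or `"plr"` (luminance steps).
#' @return A list with elements `samples` (data frame: `run_id`, `t_ms`,
#'   `xL`, `yL`, `pL`, `validL`, `xR`, `yR`, `pR`, `validR`), `events`
#'   (data frame: `t_ms`, `run_id`, `type`, `effector`), and `truth`
#'   (ground-truth list: true saccade table, event table with per-event
#'   amplitudes, blink intervals, tabulated rate profile and pupil kernel).
#' @export
render_session <- function(config, task = c("motor", "plr")) {
  task <- match.arg(task)
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$sampling_rate
  dt <- 1 / fs
  n_run <- round(config$run_duration * fs)
  gap_ms <- 5000
  run_len_ms <- round(config$run_duration * 1000)

  samples_l <- list()
  events_l <- list()
  truth_sacc <- list()
  truth_ev <- list()

  if (config$n_runs == 0) {
    samples <- data.frame(run_id = character(0), t_ms = integer(0),
                          xL = numeric(0), yL = numeric(0), pL = numeric(0),
                          validL = logical(0), xR = numeric(0), yR = numeric(0),
                          pR = numeric(0), validR = logical(0),
                          stringsAsFactors = FALSE)
    events <- data.frame(t_ms = integer(0), run_id = character(0),
                         type = character(0), effector = character(0),
                         stringsAsFactors = FALSE)
    truth <- list(saccades = data.frame(), events = data.frame(),
                  blinks = data.frame(), config = config)
    return(list(samples = samples, events = events, truth = truth))
  }

  for (r in seq_len(config$n_runs)) {
    run_id <- sprintf("run%02d", r)
    start_ms <- (r - 1L) * (run_len_ms + gap_ms)
    t_ms <- start_ms + seq_len(n_run) - 1L

    if (task == "motor") {
      # self-paced presses: cumulative truncated-exponential intervals
      iv <- sample_intervals(config$interval_scale, config$interval_lo,
                             config$interval_hi,
                             n = ceiling(config$run_duration / config$interval_lo) + 2)
      ev_s <- round(cumsum(iv) * 1000) / 1000  # quantize to the 1-ms grid
      ev_s <- ev_s[ev_s < config$run_duration - 1.5]
      ev_type <- rep("press", length(ev_s))
    } else {
      iv <- sample_intervals(config$interval_scale, config$interval_lo,
                             config$interval_hi,
                             n = ceiling(config$run_duration / config$interval_lo) + 2)
      ev_s <- round(cumsum(iv) * 1000) / 1000
      ev_s <- ev_s[ev_s < config$run_duration - 1.5]
      ev_type <- rep(c("lum_increment", "lum_decrement"),
                     length.out = length(ev_s))
    }
    n_ev <- length(ev_s)

    # per-event amplitude factors
    amp_ev <- rep(1, n_ev)
    if (task == "motor" && n_ev > 0) {
      if (config$coupling_mode == "shared" && config$coupling_sd > 0) {
        # log-normal factor, capped so the suppressed rate never clips at 0,
        # rescaled back to unit mean
        amp_ev <- pmin(stats::rlnorm(n_ev, -config$coupling_sd^2 / 2,
                                     config$coupling_sd), AMP_CAP) /
          capped_lnorm_mean(config$coupling_sd)
      } else if (config$coupling_mode == "interval") {
        pre <- c(ev_s[1], diff(ev_s))
        amp_ev <- pmax(0.1, 1 + 0.4 * (pre - mean(pre)) / max(stats::sd(pre), 1e-9))
      }
    }

    # saccade times
    if (task == "motor") {
      sts <- simulate_saccade_times(ev_s, config$run_duration,
                                    config$baseline_saccade_rate,
                                    profile = function(tau) rate_modulation(tau, config),
                                    event_amplitude = amp_ev)
    } else {
      sts <- simulate_saccade_times(numeric(0), config$run_duration,
                                    config$baseline_saccade_rate)
    }
    sts <- sts[sts > 0.06 & sts < config$run_duration - 0.12]
    ns <- length(sts)

    # kinematics
    amp_arcmin <- draw_truncated_lnorm(ns, log(config$amp_median_arcmin),
                                       config$amp_sigma, config$amp_range)
    dur_ms <- round(draw_truncated_lnorm(ns, log(config$dur_median_ms),
                                         config$dur_sigma, config$dur_range))
    theta <- stats::rnorm(ns, 0, config$dir_sd_deg)

    # ballistic gaze rendering via velocity increments + single cumsum
    incx <- numeric(n_run)
    incy <- numeric(n_run)
    dir_deg <- numeric(ns)
    cur_x <- 0
    if (ns > 0) {
      ord <- order(sts)
      sts <- sts[ord]; amp_arcmin <- amp_arcmin[ord]
      dur_ms <- dur_ms[ord]; theta <- theta[ord]
      for (k in seq_len(ns)) {
        # corrective tendency: saccade toward screen center most of the time
        sgn <- if (stats::runif(1) < 0.75) -sign(cur_x + 1e-12) else sign(cur_x + 1e-12)
        if (sgn == 0) sgn <- sample(c(-1, 1), 1)
        a_deg <- amp_arcmin[k] / 60
        dx <- a_deg * cos(theta[k] * pi / 180) * sgn
        dy <- a_deg * sin(theta[k] * pi / 180)
        dir_deg[k] <- atan2(dy, dx) * 180 / pi
        i0 <- round(sts[k] * fs) + 1L
        len <- max(2L, dur_ms[k])
        i1 <- min(n_run, i0 + len - 1L)
        prof <- minjerk_steps(i1 - i0 + 1L)
        incx[i0:i1] <- incx[i0:i1] + dx * prof
        incy[i0:i1] <- incy[i0:i1] + dy * prof
        cur_x <- cur_x + dx
      }
    }
    gx <- cumsum(incx)
    gy <- cumsum(incy)

    # pupil change-rate signal: superposed kernels
    tg <- (seq_len(n_run) - 1) * dt
    cr <- numeric(n_run)
    if (n_ev > 0) {
      for (i in seq_len(n_ev)) {
        idx <- which(tg >= ev_s[i] - 2.5 & tg <= ev_s[i] + 3.5)
        if (!length(idx)) next
        tau <- tg[idx] - ev_s[i]
        if (task == "motor") {
          cr[idx] <- cr[idx] + amp_ev[i] * pupil_kernel_fun(tau, config)
        } else {
          cr[idx] <- cr[idx] + plr_kernel_fun(tau, config, ev_type[i])
        }
      }
    }
    if (config$run_onset_amp != 0) {
      idx <- which(tg <= 4)
      cr[idx] <- cr[idx] + run_onset_kernel_fun(tg[idx], config)
    }
    p_true <- config$pupil_baseline + cumsum(cr) * dt
    if (config$tonic_drift_mm > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      tg_abs <- t_ms / 1000
      p_true <- p_true + config$tonic_drift_mm *
        (sin(2 * pi * tg_abs / 23 + ph[1]) + 0.8 * sin(2 * pi * tg_abs / 41 + ph[2]))
    }

    sg <- config$noise_sd_gaze
    sp <- config$noise_sd_pupil
    samples_l[[r]] <- data.frame(
      run_id = run_id, t_ms = t_ms,
      xL = gx + stats::rnorm(n_run, 0, sg), yL = gy + stats::rnorm(n_run, 0, sg),
      pL = p_true + stats::rnorm(n_run, 0, sp), validL = TRUE,
      xR = gx + stats::rnorm(n_run, 0, sg), yR = gy + stats::rnorm(n_run, 0, sg),
      pR = p_true + stats::rnorm(n_run, 0, sp), validR = TRUE,
      stringsAsFactors = FALSE)

    ev_ms <- start_ms + round(ev_s * 1000)
    events_l[[r]] <- data.frame(
      t_ms = c(start_ms, ev_ms, start_ms + run_len_ms),
      run_id = run_id,
      type = c("run_start", ev_type, "run_end"),
      effector = c("none", rep(if (task == "motor") config$effector else "none", n_ev), "none"),
      stringsAsFactors = FALSE)

    truth_sacc[[r]] <- data.frame(run_id = run_id,
                                  t_ms = start_ms + sts * 1000,
                                  amplitude_arcmin = amp_arcmin,
                                  duration_ms = dur_ms,
                                  direction_deg = dir_deg,
                                  stringsAsFactors = FALSE)
    truth_ev[[r]] <- data.frame(run_id = run_id, t_ms = ev_ms, type = ev_type,
                                amplitude = amp_ev, stringsAsFactors = FALSE)
  }

  samples <- do.call(rbind, samples_l)
  events <- do.call(rbind, events_l)
  rownames(samples) <- rownames(events) <- NULL

  blinks <- data.frame(run_id = character(0), start_ms = numeric(0),
                       end_ms = numeric(0), stringsAsFactors = FALSE)
  if (config$blink_rate > 0) {
    bl <- inject_blinks(samples, config$blink_rate)
    samples <- bl$samples
    blinks <- bl$blinks
  }

  tau_tab <- seq(-2.5, 3, by = 0.005)
  truth <- list(
    saccades = do.call(rbind, truth_sacc),
    events = do.call(rbind, truth_ev),
    blinks = blinks,
    rate_profile = data.frame(tau_s = tau_tab,
                              rate = config$baseline_saccade_rate *
                                rate_modulation(tau_tab, config)),
    pupil_kernel = data.frame(tau_s = tau_tab,
                              value = pupil_kernel_fun(tau_tab, config)),
    config = config)
  rownames(truth$saccades) <- rownames(truth$events) <- NULL
  list(samples = samples, events = events, truth = truth)
}

#' Inject blinks into a rendered session
#'
#' Inserts blink artifacts, time-locked across the two eyes: a rapid linear
#' pupil collapse, a gap of missing samples (pupil and gaze `NA`, validity
#' `FALSE`), and a rapid recovery. Blink placement avoids run boundaries and
#' other blinks.
#'
#' @param samples a samples data frame as produced by [render_session()].
#' @param blink_rate blinks per minute.
#' @param seed optional integer seed (the session RNG stream is used when
#'   `NULL`).
#' @param collapse_ms,gap_ms duration (ms) of each collapse/recovery ramp and
#'   of the missing-data gap.
#' @param drop_mm pupil collapse depth (mm).
#' @return A list with modified `samples` and a `blinks` data frame
#'   (`run_id`, `start_ms`, `end_ms`).
#' @export
inject_blinks <- function(samples, blink_rate, seed = NULL,
                          collapse_ms = 40, gap_ms = 100, drop_mm = 2.5) {
  stopifnot(blink_rate >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (blink_rate == 0 || nrow(samples) == 0) {
    return(list(samples = samples,
                blinks = data.frame(run_id = character(0), start_ms = numeric(0),
                                    end_ms = numeric(0), stringsAsFactors = FALSE)))
  }
  total_ms <- 2 * collapse_ms + gap_ms
  bl <- list()
  for (run in unique(samples$run_id)) {
    idx <- which(samples$run_id == run)
    n <- length(idx)
    dur_min <- n / 1000 / 60
    nb <- stats::rpois(1, blink_rate * dur_min)
    if (nb == 0) next
    onsets <- sort(round(stats::runif(nb, 600, n - 600 - total_ms)))
    if (length(onsets) > 1)
      onsets <- onsets[c(TRUE, diff(onsets) > total_ms + 800)]
    for (o in onsets) {
      i_col <- idx[o:(o + collapse_ms - 1)]
      i_gap <- idx[(o + collapse_ms):(o + collapse_ms + gap_ms - 1)]
      i_rec <- idx[(o + collapse_ms + gap_ms):(o + total_ms - 1)]
      ramp <- seq_len(collapse_ms) / collapse_ms
      for (eye in c("L", "R")) {
        pc <- paste0("p", eye)
        samples[i_col, pc] <- samples[i_col, pc] - drop_mm * ramp
        samples[i_rec, pc] <- samples[i_rec, pc] - drop_mm * rev(ramp)
        samples[i_gap, pc] <- NA_real_
        samples[i_gap, paste0("x", eye)] <- NA_real_
        samples[i_gap, paste0("y", eye)] <- NA_real_
        samples[i_gap, paste0("valid", eye)] <- FALSE
      }
      bl[[length(bl) + 1]] <- data.frame(run_id = run,
                                         start_ms = samples$t_ms[i_col[1]],
                                         end_ms = samples$t_ms[i_rec[length(i_rec)]],
                                         stringsAsFactors = FALSE)
    }
  }
  blinks <- if (length(bl)) do.call(rbind, bl) else
    data.frame(run_id = character(0), start_ms = numeric(0), end_ms = numeric(0),
               stringsAsFactors = FALSE)
  rownames(blinks) <- NULL
  list(samples = samples, blinks = blinks)
}

#' Injected rate curve on the analysis grid
#'
#' The ground-truth event-locked saccade rate the generator realizes, on the
#' analysis' 25-ms bins, optionally smoothed with the same 250-ms boxcar as
#' [smooth_rate_curve()]. The curve averages the modulated intensity over
#' the per-event amplitude distribution, applies the exact dead-time
#' correction `lambda / (1 + lambda * dead_time)` implied by the generator's
#' refractory gap (an increasing transform, so extremum locations are those
#' of the raw modulation profile), and accounts for the analysis convention
#' of timestamping each saccade at the midpoint of its start and end, which
#' delays the observed curve by half a saccade duration (the curve is
#' convolved with the generator's duration/2 distribution).
#'
#' @param config a [sim_config()].
#' @param window peri-event window (s).
#' @param bin_s bin width (s).
#' @param smooth apply the 10-bin boxcar.
#' @param dead_time_s the generator's refractory gap (s).
#' @return Data frame with `offset_s` (bin centers) and `rate` (saccades/s).
#' @export
injected_rate_curve <- function(config, window = c(-2.5, 3), bin_s = 0.025,
                                smooth = TRUE, dead_time_s = 0.025) {
  edges <- seq(window[1], window[2], by = bin_s)
  nb <- length(edges) - 1
  a_grid <- amplitude_quadrature(config)
  # quantiles of the midpoint delay (half the truncated log-normal duration)
  plo <- stats::plnorm(config$dur_range[1], log(config$dur_median_ms),
                       config$dur_sigma)
  phi <- stats::plnorm(config$dur_range[2], log(config$dur_median_ms),
                       config$dur_sigma)
  pq <- plo + ((seq_len(21) - 0.5) / 21) * (phi - plo)
  half_dur_s <- stats::qlnorm(pq, log(config$dur_median_ms),
                              config$dur_sigma) / 2000
  rate <- vapply(seq_len(nb), function(b) {
    tt <- seq(edges[b], edges[b + 1], length.out = 51)
    tt <- rep(tt, times = length(half_dur_s)) -
      rep(half_dur_s, each = 51)          # onset times seen at midpoint tt
    m <- rate_modulation(tt, config)
    lam <- pmax(config$baseline_saccade_rate *
                  (outer(m - 1, a_grid) + 1), 0)  # lambda_a = base * (1 + a(m-1))
    mean(lam / (1 + lam * dead_time_s))
  }, numeric(1))
  if (smooth) {
    sm <- vapply(seq_len(nb), function(b) {
      i <- max(1, b - 5):min(nb, b + 4)
      mean(rate[i])
    }, numeric(1))
    rate <- sm
  }
  data.frame(offset_s = (edges[-1] + edges[-length(edges)]) / 2, rate = rate)
}
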