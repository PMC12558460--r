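#' Parameter-recovery studies against the synthetic generator
#'
#' These functions re-run the full pipeline on freshly simulated sessions
#' with known ground truth and quantify how well each stage recovers what
#' was injected. They are the package's built-in validation suite; the
#' problem sizes default to the ones used in the shipped checks.
#'
#' @name validation
NULL

match_saccades <- function(truth, detected, slack_ms = 5) {
  t0 <- truth$t_ms - slack_ms
  t1 <- truth$t_ms + truth$duration_ms + slack_ms
  hit <- logical(nrow(truth))
  used <- logical(nrow(detected))
  for (i in seq_len(nrow(truth))) {
    ov <- which(detected$start_ms <= t1[i] & detected$end_ms >= t0[i] &
                  detected$run_id == truth$run_id[i])
    if (length(ov)) {
      hit[i] <- TRUE
      used[ov] <- TRUE
    }
  }
  list(hit = hit, used = used)
}

#' @describeIn validation Detector recovery on artifact-free sessions:
#'   sensitivity against injected saccades and the false-alarm rate per
#'   second of recording. Sessions use the generator's nominal tracker noise
#'   floor with pupil noise and blinks disabled.
#' @param n_sessions,seed study size and master seed.
#' @export
validate_detector <- function(n_sessions = 4, seed = 1L) {
  n_true <- n_hit <- n_fa <- 0
  total_s <- 0
  for (k in seq_len(n_sessions)) {
    cfg <- sim_config(noise_sd_pupil = 0, blink_rate = 0,
                      seed = seed + 100L * k)
    s <- render_session(cfg)
    det <- detect_saccades(s$samples)
    m <- match_saccades(s$truth$saccades, det)
    n_true <- n_true + nrow(s$truth$saccades)
    n_hit <- n_hit + sum(m$hit)
    n_fa <- n_fa + sum(!m$used)
    total_s <- total_s + cfg$n_runs * cfg$run_duration
  }
  list(sensitivity = n_hit / n_true, false_alarm_rate = n_fa / total_s,
       n_true = n_true)
}

#' @describeIn validation Rate-curve recovery: simulates a cohort with the
#'   default suppression/rebound profile, runs the saccade-rate pipeline,
#'   and reports the fraction of bins where the across-participant mean
#'   smoothed curve lies within 2 standard errors of the injected profile,
#'   together with the cluster test against baseline. Sessions are simulated
#'   without blinks (the blink round trip is validated separately; the
#'   10-ms blink-proximity discard would otherwise thin the rate uniformly).
#'   The study is replicated `n_replicates` times: the per-bin coverage
#'   proportion of a single cohort is itself a random quantity (the
#'   participants' Poisson saccade counts move all bins coherently, so its
#'   sampling s.d. is several percentage points), and the replicate mean
#'   estimates its expectation; the cluster flags must hold in every
#'   replicate.
#' @param n_participants cohort size.
#' @param n_iter Monte Carlo iterations for the cluster test.
#' @param n_replicates independent cohorts to average the coverage over.
#' @export
validate_rate_recovery <- function(n_participants = 30, seed = 1L,
                                   n_iter = 1000, n_replicates = 3) {
  cfg0 <- sim_config(blink_rate = 0, seed = seed)
  pcfg <- pipeline_config(pupil = list(enabled = FALSE))
  offsets <- injected_rate_curve(cfg0)$offset_s
  injected <- injected_rate_curve(cfg0)$rate
  coverage <- numeric(n_replicates)
  neg_pre <- pos_post <- logical(n_replicates)
  clusters <- NULL
  mean_curve <- NULL
  for (rep_ in seq_len(n_replicates)) {
    curves <- matrix(NA_real_, n_participants, 220)
    baselines <- numeric(n_participants)
    for (p in seq_len(n_participants)) {
      s <- render_session(sim_config(blink_rate = 0,
                                     seed = seed + 50000L * rep_ + 1000L * p))
      res <- analyze_session(s$samples, s$events, pcfg)
      curves[p, ] <- res$smoothed$rate
      baselines[p] <- res$curve$baseline
    }
    mn <- colMeans(curves)
    se <- apply(curves, 2, stats::sd) / sqrt(n_participants)
    coverage[rep_] <- mean(abs(mn - injected) <= 2 * se, na.rm = TRUE)
    mc <- monte_carlo_p(curves, baselines, n_iter = n_iter,
                        seed = seed + 17L + rep_, offsets = offsets)
    cl <- mc$clusters
    neg_pre[rep_] <- any(cl$sign < 0 & cl$mc_p < 0.05 & cl$end > -1 & cl$start < 0)
    pos_post[rep_] <- any(cl$sign > 0 & cl$mc_p < 0.05 & cl$end > 0.2 & cl$start < 1.2)
    if (rep_ == 1) {
      clusters <- mc
      mean_curve <- data.frame(offset_s = offsets, rate = mn, se = se,
                               injected = injected)
    }
  }
  list(coverage = mean(coverage), coverage_replicates = coverage,
       clusters = clusters, neg_pre_cluster = all(neg_pre),
       pos_post_cluster = all(pos_post), mean_curve = mean_curve)
}

#' @describeIn validation Deconvolution recovery: kernel RMSE relative to
#'   the injected kernel peak for noiseless well-separated events, and the
#'   RMSE ratio of the ridge deconvolution to naive event-locked averaging
#'   when events overlap at truncated-exponential spacing.
#' @export
validate_deconvolution <- function(seed = 1L) {
  clean <- list(noise_sd_gaze = 0, noise_sd_pupil = 0, tonic_drift_mm = 0,
                blink_rate = 0, coupling_mode = "none", run_onset_amp = 0)
  fit_one <- function(cfg) {
    s <- render_session(cfg)
    pre <- preprocess_session(s$samples)
    runs <- run_table(s$events)
    frames <- downsample_frames(pre$change_rate, pre$t_ms, pre$run_id, runs)
    X <- build_design(s$events, list(press = c(-2, 5.5)), frames, runs)
    fit <- fit_deconvolution(X, frames$value)
    naive <- naive_event_average(s$events, "press", c(-2, 5.5), frames, runs)
    truth <- pupil_kernel_fun(fit$kernels$press$offset_s, cfg)
    list(glm = fit$kernels$press$value, naive = naive$value, truth = truth)
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))

  # widely separated events: no overlap at all
  sep <- do.call(sim_config, c(clean, list(interval_scale = 20, interval_lo = 11,
                                           interval_hi = 13, n_runs = 10,
                                           seed = seed + 31L)))
  a <- fit_one(sep)
  peak <- max(abs(a$truth))

  # the task's own spacing: responses overlap heavily
  ovl <- do.call(sim_config, c(clean, list(n_runs = 10, seed = seed + 32L)))
  b <- fit_one(ovl)
  list(rmse_separated_frac = rmse(a$glm, a$truth) / peak,
       rmse_glm = rmse(b$glm, b$truth), rmse_naive = rmse(b$naive, b$truth),
       rmse_ratio = rmse(b$glm, b$truth) / rmse(b$naive, b$truth))
}

#' @describeIn validation Type-I calibration of the cluster test: simulates
#'   null datasets (constant saccade rate, no event-locked modulation) and
#'   reports the fraction of datasets in which any cluster reaches
#'   `mc_p < 0.05`.
#' @param n_datasets,n_events null-study size.
#' @export
validate_cluster_null <- function(n_datasets = 200, n_participants = 20,
                                  n_events = 60, n_iter = 200, seed = 1L) {
  dur_s <- 320
  ev_template <- function(sd) {
    iv <- sample_intervals(4.6, 3, 8, n_events + 5, seed = sd)
    press <- round(cumsum(iv) * 1000)
    press <- press[press < dur_s * 1000 - 3500][seq_len(n_events)]
    make <- data.frame(t_ms = c(0, press, dur_s * 1000), run_id = "run01",
                       type = c("run_start", rep("press", length(press)), "run_end"),
                       effector = "none", stringsAsFactors = FALSE)
    make
  }
  any_sig <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    curves <- matrix(NA_real_, n_participants, 220)
    baselines <- numeric(n_participants)
    for (p in seq_len(n_participants)) {
      sd_p <- seed + 1009L * d + 13L * p
      ev <- ev_template(sd_p)
      ts <- simulate_saccade_times(numeric(0), dur_s, 0.89, seed = sd_p + 1L)
      sacc <- data.frame(run_id = "run01", timestamp_ms = ts * 1000)
      curve <- event_rate_curve(sacc, merge_presses(ev), run_table(ev))
      curves[p, ] <- smooth_rate_curve(curve)$rate
      baselines[p] <- curve$baseline
    }
    mc <- monte_carlo_p(curves, baselines, n_iter = n_iter, seed = seed + d)
    any_sig[d] <- nrow(mc$clusters) > 0 && any(mc$clusters$mc_p < 0.05)
  }
  list(false_positive_rate = mean(any_sig), n_datasets = n_datasets)
}

#' @describeIn validation Covariation recovery: simulates a cohort, runs the
#'   full per-participant pipeline (detection, metrics, regression), and
#'   returns the across-participant group test of the standardized
#'   coefficients.
#' @param coupling_mode generator coupling (`"shared"`, `"interval"` or
#'   `"none"`).
#' @param n_runs runs per participant.
#' @export
validate_covariation <- function(n_participants = 30, n_runs = 7,
                                 coupling_mode = "shared", seed = 1L) {
  pcfg <- pipeline_config(pupil = list(enabled = FALSE))
  coefs <- matrix(NA_real_, n_participants, 4,
                  dimnames = list(NULL, c("pupil_mod", "tonic_pupil",
                                          "interval_pre", "interval_post")))
  for (p in seq_len(n_participants)) {
    cfg <- sim_config(n_runs = n_runs, coupling_mode = coupling_mode,
                      seed = seed + 1000L * p)
    s <- render_session(cfg)
    res <- analyze_session(s$samples, s$events, pcfg)
    if (!res$regression$excluded) coefs[p, ] <- res$regression$coef
  }
  list(group = group_coefficient_test(coefs),
       n_included = sum(stats::complete.cases(coefs)))
}

#' @describeIn validation Specificity of the covariation test: replicate
#'   suites simulated without any saccade--pupil coupling; returns, for each
#'   predictor, the fraction of suites in which its group test stays
#'   non-significant at `alpha`.
#' @param n_suites number of replicate suites.
#' @param alpha significance level for the null check.
#' @export
validate_covariation_null <- function(n_suites = 40, n_participants = 12,
                                      n_runs = 4, alpha = 0.01, seed = 1L) {
  clean <- matrix(NA, n_suites, 4)
  for (s in seq_len(n_suites)) {
    cv <- validate_covariation(n_participants, n_runs, coupling_mode = "none",
                               seed = seed + 100000L * s)
    clean[s, ] <- cv$group$p >= alpha
    colnames(clean) <- cv$group$predictor
  }
  list(clean_fraction = colMeans(clean), n_suites = n_suites)
}

#' @describeIn validation Latency recovery: the generator pupil kernel is
#'   time-shifted so its analytic extremum sits a target lag after the
#'   analytic extremum of the injected (binned and smoothed) rate profile;
#'   the pipeline then has to measure that lag back from simulated sessions.
#'   Also recovers the light-reflex latency from a separate luminance-step
#'   cohort.
#' @param target_lag_s injected rate-to-pupil lag (s).
#' @details For `validate_latency()` the cohort uses a sharpened modulation
#'   (deep suppression, a rebound only as wide as the smoothing boxcar) so
#'   that the injected rate extrema are single well-defined bins rather than
#'   plateaus; with the default boxcar rebound the smoothed peak is flat and
#'   its location is not identified.
#' @export
validate_latency <- function(n_participants = 24, target_lag_s = 0.3,
                             seed = 1L) {
  base <- sim_config(coupling_mode = "none", noise_sd_pupil = 0,
                     tonic_drift_mm = 0, blink_rate = 0,
                     suppression_depth = 0.8, rebound_gain = 1.2,
                     rebound_window = c(0.2, 0.45))
  inj <- injected_rate_curve(base)
  rate_min <- curve_extremum(inj$offset_s, inj$rate, c(-1, 0.2), "min")$offset
  rate_peak <- curve_extremum(inj$offset_s, inj$rate, c(0, 1.2), "max")$offset

  # analytic kernel extrema on the 1/30-s analysis grid
  koff <- -2 + (0:floor(7.5 * 30)) / 30
  kval <- pupil_kernel_fun(koff, base)
  k_peak <- curve_extremum(koff, kval, c(-1, 0.5), "max")$offset
  shift <- (rate_min + target_lag_s) - k_peak
  pk <- base$pupil_kernel
  pk$dilate_peak <- pk$dilate_peak + shift
  pk$constrict_peak <- pk$constrict_peak + shift
  kval2 <- pupil_kernel_fun(koff, sim_config(pupil_kernel = pk))
  injected_pre <- (curve_extremum(koff, kval2, c(-1, 0.5), "max")$offset -
                     rate_min) * 1000
  injected_post <- (curve_extremum(koff, kval2, c(0, 2), "min")$offset -
                      rate_peak) * 1000

  pcfg <- pipeline_config()
  curves <- matrix(NA_real_, n_participants, 220)
  kmat <- matrix(NA_real_, n_participants, length(koff))
  for (p in seq_len(n_participants)) {
    cfg <- sim_config(coupling_mode = "none", noise_sd_pupil = 0,
                      tonic_drift_mm = 0, blink_rate = 0, pupil_kernel = pk,
                      suppression_depth = 0.8, rebound_gain = 1.2,
                      rebound_window = c(0.2, 0.45),
                      seed = seed + 1000L * p)
    s <- render_session(cfg)
    res <- analyze_session(s$samples, s$events, pcfg)
    curves[p, ] <- res$smoothed$rate
    kmat[p, ] <- res$deconvolution$kernels$press$value
  }
  lag <- withCallingHandlers(
    modulation_lag(inj$offset_s, colMeans(curves), koff, colMeans(kmat)),
    warning = function(w) invokeRestart("muffleWarning"))

  # light-reflex cohort
  plr_k <- matrix(NA_real_, 10, 121)
  for (p in 1:10) {
    cfg <- sim_config(n_runs = 5, noise_sd_pupil = 0.001, tonic_drift_mm = 0,
                      blink_rate = 0, seed = seed + 333L * p)
    s <- render_session(cfg, task = "plr")
    pre <- preprocess_session(s$samples)
    runs <- run_table(s$events)
    frames <- downsample_frames(pre$change_rate, pre$t_ms, pre$run_id, runs)
    X <- build_design(s$events, list(lum_increment = c(0, 4),
                                     lum_decrement = c(0, 4),
                                     run_start = c(0, 5.5)), frames, runs)
    fit <- fit_deconvolution(X, frames$value)
    plr_k[p, ] <- fit$kernels$lum_increment$value
  }
  plr_ms <- plr_latency(data.frame(offset_s = (0:120) / 30,
                                   value = colMeans(plr_k)))
  list(pre_lag_ms = lag$pre_lag_ms, post_lag_ms = lag$post_lag_ms,
       injected_pre_ms = injected_pre, injected_post_ms = injected_post,
       pre_error_ms = lag$pre_lag_ms - injected_pre,
       post_error_ms = lag$post_lag_ms - injected_post,
       plr_latency_ms = plr_ms)
}
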