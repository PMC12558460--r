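#' Default pipeline configuration
#'
#' Returns the fully populated configuration list consumed by
#' [run_pipeline()]: simulation settings (forwarded to [sim_config()]),
#' per-stage parameters, stage toggles, the nuisance-model selector for the
#' pupil deconvolution, an output directory, and the master seed. Every key
#' is schema-checked; unknown keys are rejected by name.
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `simulate = list(n_participants = 8)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(n_participants = 8),
    sim = list(),                 # overrides passed to sim_config()
    preprocess = list(change_threshold = 25, merge_gap = 50, pad = 20, win = 50),
    saccades = list(lambda = 6, min_dur_ms = 6),
    rate = list(window = c(-2.5, 3), bin_s = 0.025, smooth_ms = 250,
                pre = c(-0.8, 0), post = c(0.2, 1.2)),
    pupil = list(enabled = TRUE, nuisance = "runstart",
                 press_window = c(-2, 5.5), runstart_window = c(0, 5.5),
                 blink_window = c(0, 4), saccade_window = c(0, 2),
                 penalty_grid = c(0.1, 1, 10),
                 dilation = c(-0.6, 0.2), constriction = c(0.6, 1.6)),
    stats = list(n_iter = 1000, alpha = 0.05),
    covary = list(min_events = 10, tonic_width_s = 30),
    latency = list(windows = list(rate_min = c(-1, 0.2), pupil_peak = c(-1, 0.5),
                                  rate_peak = c(0, 1.2), pupil_min = c(0, 2))))
  cfg <- merge_config(cfg, list(...), path = "")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, override, path) {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key: '%s'", full))
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]])) && full != "sim" && full != "latency.windows") {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL   # output location does not change the analysis
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a cohort of participants
#'
#' Renders one session per participant with seeds derived deterministically
#' from `base_seed`.
#'
#' @param n_participants cohort size.
#' @param base_seed master seed.
#' @param ... overrides forwarded to [sim_config()].
#' @param task forwarded to [render_session()].
#' @return List of sessions (each a `render_session()` result).
#' @export
simulate_cohort <- function(n_participants, base_seed = 1L, ..., task = "motor") {
  lapply(seq_len(n_participants), function(p) {
    cfg <- sim_config(..., seed = base_seed + 1000L * p)
    render_session(cfg, task = task)
  })
}

#' Analyze one session end to end
#'
#' Runs preprocessing, saccade detection, press merging, the event-locked
#' rate curve (raw and smoothed), per-event metrics, the tonic pupil series,
#' the per-event covariation table and regression, and (optionally) the
#' press-locked pupil deconvolution.
#'
#' @param samples,events one session's data frames.
#' @param config a `pipeline_config` (defaults used when `NULL`).
#' @return A list of per-session results.
#' @export
analyze_session <- function(samples, events, config = NULL) {
  if (is.null(config)) config <- pipeline_config()
  pp <- config$preprocess
  pre <- preprocess_session(samples, pp$change_threshold, pp$merge_gap,
                            pp$pad, pp$win)
  sacc <- detect_saccades(samples, pre$blinks, config$saccades$lambda,
                          config$saccades$min_dur_ms)
  motor <- merge_presses(events)
  runs <- run_table(events)
  rc <- config$rate
  curve <- event_rate_curve(sacc, motor, runs, rc$window, rc$bin_s)
  smoothed <- smooth_rate_curve(curve, rc$smooth_ms)
  rate_metrics <- per_event_rate_metric(sacc, motor, rc$pre, rc$post)
  pupil_metrics <- per_event_pupil_metric(pre$change_rate, pre$t_ms, motor,
                                          config$pupil$dilation,
                                          config$pupil$constriction)
  tonic <- tonic_pupil(pre$pupil, pre$t_ms, pre$run_id,
                       config$covary$tonic_width_s)
  tab <- build_event_table(motor, rate_metrics, pupil_metrics, tonic, pre$t_ms)
  reg <- fit_participant_regression(tab, config$covary$min_events)
  decon <- NULL
  if (isTRUE(config$pupil$enabled)) {
    pu <- config$pupil
    decon <- fit_session_deconvolution(pre, events, sacc,
                                       nuisance = pu$nuisance,
                                       press_window = pu$press_window,
                                       runstart_window = pu$runstart_window,
                                       blink_window = pu$blink_window,
                                       saccade_window = pu$saccade_window,
                                       penalty_grid = pu$penalty_grid)
  }
  list(preprocessed = pre, saccades = sacc, motor_events = motor,
       curve = curve, smoothed = smoothed, rate_metrics = rate_metrics,
       pupil_metrics = pupil_metrics, event_table = tab, regression = reg,
       deconvolution = decon)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Orchestrates the stages in dependency order for a simulated cohort:
#' session generation, per-participant analysis ([analyze_session()]),
#' group-level cluster statistics on the saccade-rate curves (and on the
#' pupil kernels when the deconvolution is enabled), the across-participant
#' covariation test, and the modulation-lag report. Rerunning with an
#' identical configuration reproduces the bundle exactly; the bundle is
#' stamped with a hash of the configuration and the seed.
#'
#' @param config a `pipeline_config` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return A results bundle (list) with per-participant and group results;
#'   written as CSV/JSON artifacts when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  sessions <- do.call(simulate_cohort,
                      c(list(n_participants = config$simulate$n_participants,
                             base_seed = config$seed), config$sim))
  per <- lapply(sessions, function(s) analyze_session(s$samples, s$events, config))

  offsets <- per[[1]]$smoothed$offset_s
  curves <- do.call(rbind, lapply(per, function(x) x$smoothed$rate))
  baselines <- vapply(per, function(x) x$curve$baseline, numeric(1))
  rate_clusters <- monte_carlo_p(curves, baselines, config$stats$n_iter,
                                 config$stats$alpha, seed = config$seed + 7L,
                                 offsets = offsets)

  kernel_mean <- NULL
  kernel_clusters <- NULL
  if (isTRUE(config$pupil$enabled)) {
    kmat <- do.call(rbind, lapply(per, function(x)
      x$deconvolution$kernels$press$value))
    koff <- per[[1]]$deconvolution$kernels$press$offset_s
    kernel_mean <- data.frame(offset_s = koff, value = colMeans(kmat))
    kernel_clusters <- monte_carlo_p(kmat, rep(0, nrow(kmat)),
                                     config$stats$n_iter, config$stats$alpha,
                                     seed = config$seed + 8L, offsets = koff)
  }

  coefs <- do.call(rbind, lapply(per, function(x) x$regression$coef))
  group <- if (sum(stats::complete.cases(coefs)) >= 2)
    group_coefficient_test(coefs) else NULL

  lags <- NULL
  if (!is.null(kernel_mean)) {
    lags <- withCallingHandlers(
      modulation_lag(offsets, colMeans(curves), kernel_mean$offset_s,
                     kernel_mean$value, config$latency$windows),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  bundle <- list(config_hash = config_hash(config), seed = config$seed,
                 n_participants = length(per), participants = per,
                 mean_curve = data.frame(offset_s = offsets,
                                         rate = colMeans(curves)),
                 rate_clusters = rate_clusters, kernel_mean = kernel_mean,
                 kernel_clusters = kernel_clusters,
                 coefficients = coefs, group_test = group, lags = lags)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$mean_curve, file.path(out_dir, "mean_rate_curve.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$kernel_mean))
    utils::write.csv(bundle$kernel_mean, file.path(out_dir, "press_kernel.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$group_test))
    utils::write.csv(bundle$group_test, file.path(out_dir, "group_regression.csv"),
                     row.names = FALSE)
  meta <- list(config_hash = bundle$config_hash, seed = bundle$seed,
               n_participants = bundle$n_participants,
               rate_clusters = bundle$rate_clusters$clusters,
               lags = bundle$lags)
  jsonlite::write_json(meta, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
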