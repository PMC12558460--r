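frames_for <- function(ev, x = NULL) {
  runs <- run_table(ev)
  n <- sum(runs$end_ms - runs$start_ms)
  if (is.null(x)) x <- rep(0, n)
  t_ms <- unlist(lapply(seq_len(nrow(runs)),
                        function(r) runs$start_ms[r]:(runs$end_ms[r] - 1)))
  run_id <- rep(runs$run_id, runs$end_ms - runs$start_ms)
  downsample_frames(x, t_ms, run_id, runs)
}

test_that("frame downsampling is the blockwise mean", {
  ev <- make_events(numeric(0), run_end = 1000)
  fr <- frames_for(ev, rep(2.5, 1000))
  expect_equal(nrow(fr), 30)          # one second -> 30 frames
  expect_equal(fr$value, rep(2.5, 30))

  set.seed(80)
  x <- rnorm(3000)
  ev2 <- make_events(numeric(0), run_end = 3000)
  fr2 <- frames_for(ev2, x)
  oracle <- as.numeric(tapply(x, floor((0:2999) * 30 / 1000), mean))
  expect_equal(fr2$value, oracle)

  # frames whose samples are all missing are NA
  x[100:140] <- NA
  fr3 <- frames_for(ev2, x)
  expect_true(is.na(fr3$value[4]))    # frame [100, 133) fully missing
})

test_that("the staggered design places ones at event-shifted frames", {
  ev <- make_events(numeric(0), run_end = 10000)
  fr <- frames_for(ev)
  runs <- run_table(ev)
  X0 <- build_design(ev, list(press = c(0, 1)), fr, runs)
  expect_true(all(X0 == 0))

  # one press inside frame 100 with window [0, 2/30]: ones on the staggered
  # diagonal (frame 100 spans [3333.3, 3366.7) ms)
  ev1 <- make_events(3340, run_end = 10000)
  X1 <- build_design(ev1, list(press = c(0, 2 / 30)), fr, runs)
  expect_equal(dim(X1), c(300, 3))
  expect_equal(which(X1[, 1] == 1), 101)
  expect_equal(which(X1[, 2] == 1), 102)
  expect_equal(which(X1[, 3] == 1), 103)
  expect_equal(sum(X1), 3)

  # column sums count the events whose shifted time lands in-bounds
  set.seed(81)
  press <- sort(sample(500:9500, 12))
  ev2 <- make_events(press, run_end = 10000)
  X2 <- build_design(ev2, list(press = c(-2, 5.5)), fr, runs)
  offs <- attr(X2, "offset_s")
  oracle <- sapply(offs, function(o)
    sum(press / 1000 + o >= 0 & press / 1000 + o < 10))
  expect_equal(unname(colSums(X2)), oracle)
})

test_that("ridge deconvolution recovers kernels and matches a direct solve", {
  ev <- make_events(seq(8000, 110000, by = 9000), run_end = 120000)
  fr <- frames_for(ev)
  runs <- run_table(ev)
  X <- build_design(ev, list(press = c(-2, 5.5)), fr, runs)
  K <- ncol(X)
  truth <- 0.1 * exp(-((seq_len(K) / 30 - 2.3)^2) / 0.2) -
    0.07 * exp(-((seq_len(K) / 30 - 4)^2) / 0.4)

  # zero response -> exactly zero kernels
  f0 <- fit_deconvolution(X, rep(0, nrow(X)))
  expect_equal(max(abs(f0$kernels$press$value)), 0)

  # noiseless forward simulation -> near-exact recovery
  y <- drop(X %*% truth)
  fit <- fit_deconvolution(X, y, penalty_grid = c(0.01, 1, 10))
  expect_equal(fit$penalty, 0.01)     # LOO prefers the least shrinkage
  rmse <- sqrt(mean((fit$kernels$press$value - truth)^2))
  expect_lt(rmse, 0.05 * max(abs(truth)))

  # cross-check against the penalized normal equations at a fixed penalty
  set.seed(82)
  yn <- y + rnorm(length(y), 0, 0.05)
  f1 <- fit_deconvolution(X, yn, penalty_grid = 5)
  xm <- colMeans(X); ym <- mean(yn)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) + diag(5, K), crossprod(Xc, yn - ym))
  expect_equal(f1$kernels$press$value, drop(beta), tolerance = 1e-8)

  # missing frames are dropped, not imputed
  y2 <- y; y2[40:60] <- NA
  f2 <- fit_deconvolution(X, y2, penalty_grid = c(0.01))
  expect_lt(sqrt(mean((f2$kernels$press$value - truth)^2)), 0.05 * max(abs(truth)))
  expect_error(fit_deconvolution(X, rep(NA_real_, nrow(X))), "missing")
})

test_that("an event type with no occurrences leaves the press kernel alone", {
  ev <- make_events(seq(8000, 110000, by = 9000), run_end = 120000)
  fr <- frames_for(ev)
  runs <- run_table(ev)
  X1 <- build_design(ev, list(press = c(-2, 5.5)), fr, runs)
  X2 <- build_design(ev, list(press = c(-2, 5.5), blink = c(0, 4)), fr, runs)
  truth <- sin(seq_len(ncol(X1)) / 10) * 0.05
  y <- drop(X1 %*% truth)
  k1 <- fit_deconvolution(X1, y, penalty_grid = 0.1)$kernels$press$value
  k2 <- fit_deconvolution(X2, y, penalty_grid = 0.1)$kernels$press$value
  expect_equal(k1, k2, tolerance = 1e-6)
})

test_that("run-onset transients and oculomotor nuisances leave the press kernel intact", {
  # noiseless session with a run-onset pupil transient: with the run_start
  # nuisance in the model, the press kernel stays within 5% of the injected
  # kernel peak
  cfg <- sim_config(n_runs = 5, noise_sd_gaze = 0.002, noise_sd_pupil = 0,
                    tonic_drift_mm = 0, blink_rate = 0,
                    coupling_mode = "none", run_onset_amp = 0.1, seed = 55)
  s <- render_session(cfg)
  pre <- preprocess_session(s$samples)
  fit <- fit_session_deconvolution(pre, s$events)
  k <- fit$kernels$press
  truth <- pupil_kernel_fun(k$offset_s, cfg)
  expect_lt(max(abs(k$value - truth)), 0.05 * max(abs(truth)))

  # the oculomotor-nuisance variant keeps the dilation-then-constriction
  # sign structure
  cfg2 <- sim_config(n_runs = 4, seed = 56)
  s2 <- render_session(cfg2)
  pre2 <- preprocess_session(s2$samples)
  sacc2 <- detect_saccades(s2$samples, pre2$blinks)
  fit2 <- fit_session_deconvolution(pre2, s2$events, sacc2,
                                    nuisance = "runstart+oculomotor")
  expect_true(all(c("press", "run_start", "blink", "saccade") %in%
                    names(fit2$kernels)))
  k2 <- fit2$kernels$press
  dil <- k2$offset_s >= -1 & k2$offset_s <= 0.3
  con <- k2$offset_s >= 0.5 & k2$offset_s <= 1.8
  expect_gt(max(k2$value[dil]), 0)
  expect_lt(min(k2$value[con]), 0)
})

test_that("kernel integration is the cumulative Riemann sum from zero", {
  z <- data.frame(offset_s = (0:30) / 30, value = rep(0, 31))
  expect_equal(integrate_kernel(z)$integrated, rep(0, 31))

  const <- data.frame(offset_s = (0:59) / 30, value = rep(0.3, 60))
  ic <- integrate_kernel(const)$integrated
  expect_equal(ic[1], 0)
  expect_equal(ic[60] + 0.3 / 30, 0.3 * 2)   # final value + last step = c*T

  # integrating the frame-sampled derivative of a known size curve
  # reproduces that curve up to frame tolerance
  tt <- (0:150) / 30
  size <- 0.2 * sin(tt)
  deriv <- data.frame(offset_s = tt, value = 0.2 * cos(tt))
  again <- integrate_kernel(deriv)$integrated
  expect_lt(max(abs(again - (size - size[1]))), 0.01)
})

test_that("the per-event pupil metric is the windowed-mean difference", {
  ev <- make_events(c(10000, 20000, 26000, 27500))
  events <- merge_presses(ev)
  t_ms <- 0:44999

  expect_equal(per_event_pupil_metric(rep(0, 45000), t_ms, events)[1], 0)

  # +0.1 mm/s dilation window, -0.1 constriction window -> 0.2
  cr <- rep(0, 45000)
  cr[t_ms >= 9400 & t_ms < 10200] <- 0.1
  cr[t_ms >= 10600 & t_ms < 11600] <- -0.1
  expect_equal(per_event_pupil_metric(cr, t_ms, events)[1], 0.2)

  # random signal equals the windowed-mean oracle
  set.seed(83)
  crr <- rnorm(45000)
  m <- per_event_pupil_metric(crr, t_ms, events)
  oracle <- mean(crr[t_ms >= 10000 - 600 & t_ms < 10000 + 200]) -
    mean(crr[t_ms >= 10000 + 600 & t_ms < 10000 + 1600])
  expect_equal(m[1], oracle)
  expect_true(all(is.na(m[3:4])))     # non-isolated events flagged
})
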