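test_that("truncated-exponential sampler matches its closed-form mean and CDF", {
  expect_error(sample_intervals(4.6, 8, 3, 10), "invalid")

  x <- sample_intervals(4.6, 3, 8, 2e5, seed = 11)
  expect_true(all(x >= 3 & x <= 8))

  # independent oracle: numeric integration of the conditional density
  dens <- function(t) exp(-(t - 3) / 4.6) / 4.6
  z <- stats::integrate(dens, 3, 8)$value
  mu <- stats::integrate(function(t) t * dens(t) / z, 3, 8)$value
  expect_equal(truncexp_mean(4.6, 3, 8), mu, tolerance = 1e-6)
  expect_equal(mean(x), mu, tolerance = 0.02)

  # KS distance against the closed-form CDF
  cdf <- truncexp_cdf(4.6, 3, 8)
  x2 <- sample_intervals(4.6, 3, 8, 1e5, seed = 12)
  ks <- max(abs(seq_along(x2) / length(x2) - cdf(sort(x2))))
  expect_lt(ks, 0.01)

  # degenerate range collapses to the lower bound
  eps <- sample_intervals(4.6, 3, 3 + 1e-6, 100, seed = 13)
  expect_true(all(abs(eps - 3) < 2e-6))
})

test_that("saccade-time simulation follows the prescribed intensity", {
  # zero intensity silences the process
  silent <- simulate_saccade_times(numeric(0), 45, 0, seed = 1)
  expect_length(silent, 0)
  # full suppression silences the neighborhood of an event
  sup <- simulate_saccade_times(20, 45, 5,
                                profile = function(tau)
                                  ifelse(abs(tau) < 1, 0, 1),
                                event_amplitude = 1, seed = 1)
  expect_false(any(sup > 19.02 & sup < 21))

  # Poisson count oracle for constant intensity
  ts <- simulate_saccade_times(numeric(0), 1000, 0.89, refractory_s = 0, seed = 2)
  expect_lt(abs(length(ts) - 890), 3 * sqrt(890))

  # time-rescaling theorem: rescaled intervals are Exp(1)
  cfg <- sim_config(seed = 3)
  ev <- c(5, 12, 18, 26, 33, 40)
  ts2 <- simulate_saccade_times(ev, 45, 2.5,
                                profile = function(tau) rate_modulation(tau, cfg),
                                event_amplitude = rep(1, length(ev)),
                                refractory_s = 0, dt = 0.001, seed = 4)
  # reconstruct the tabulated intensity independently of the simulator
  tg <- seq(0, 45 - 0.001, by = 0.001)
  lam <- rep(2.5, length(tg))
  for (e in ev) lam <- lam * rate_modulation(tg - e, cfg)
  Lam <- cumsum(lam) * 0.001
  resc <- diff(Lam[floor(ts2 / 0.001) + 1])
  # grid tabulation quantizes the rescaled intervals slightly; ties expected
  expect_gt(suppressWarnings(stats::ks.test(resc, "pexp"))$p.value, 0.01)

  expect_error(simulate_saccade_times(numeric(0), 10, -1), "negative")
})

test_that("rendered sessions are deterministic and respect superposition", {
  cfg <- sim_config(n_runs = 2, seed = 21)
  a <- render_session(cfg)
  b <- render_session(cfg)
  expect_identical(a, b)

  # zero noise, unit amplitudes: pupil trace must equal baseline plus the
  # integral of the superposed kernels (linear superposition, exactly)
  cfg0 <- sim_config(n_runs = 1, noise_sd_gaze = 0, noise_sd_pupil = 0,
                     tonic_drift_mm = 0, coupling_mode = "none",
                     blink_rate = 0, run_onset_amp = 0, seed = 22)
  s <- render_session(cfg0)
  tg <- (s$samples$t_ms - s$samples$t_ms[1]) / 1000
  cr <- rep(0, nrow(s$samples))
  for (e in s$truth$events$t_ms / 1000)
    cr <- cr + pupil_kernel_fun(tg - e, cfg0) *
      (tg >= e - 2.5 & tg <= e + 3.5)
  recon <- cfg0$pupil_baseline + cumsum(cr) / 1000
  expect_equal(s$samples$pL, recon, tolerance = 1e-9)
  # the kernel integrates to ~0, so the trace ends near baseline
  expect_lt(abs(s$samples$pL[nrow(s$samples)] - cfg0$pupil_baseline), 0.02)
})

test_that("empty configurations give empty sessions", {
  s <- render_session(sim_config(n_runs = 0, seed = 1))
  expect_equal(nrow(s$samples), 0)
  expect_equal(nrow(s$events), 0)
})

test_that("per-run event counts match the interval distribution", {
  cfg <- sim_config(n_runs = 10, blink_rate = 0, seed = 30)
  s <- render_session(cfg)
  per_run <- table(s$events$run_id[s$events$type == "press"])
  # usable window ~43.5 s, mean interval ~5.06 s -> about 8-9 events per run
  expect_gt(mean(per_run), 7)
  expect_lt(mean(per_run), 10)
  expect_equal(nrow(s$truth$events), sum(s$events$type == "press"))
})

test_that("true saccade kinematics match the configured distributions", {
  cfg <- sim_config(n_runs = 6, blink_rate = 0, seed = 31)
  s <- render_session(cfg)
  tr <- s$truth$saccades
  expect_gt(nrow(tr), 150)
  expect_equal(median(tr$amplitude_arcmin), 21.3, tolerance = 0.15)
  expect_equal(median(tr$duration_ms), 19, tolerance = 0.2)
  from_horiz <- pmin(abs(tr$direction_deg), abs(180 - abs(tr$direction_deg)))
  expect_gt(mean(from_horiz < 10), 0.68)
  expect_lt(mean(from_horiz < 10), 0.88)
  # every true saccade lies inside its run
  expect_true(all(tr$t_ms >= 0))
  for (run in unique(tr$run_id)) {
    rs <- s$events$t_ms[s$events$run_id == run & s$events$type == "run_start"]
    re <- s$events$t_ms[s$events$run_id == run & s$events$type == "run_end"]
    expect_true(all(tr$t_ms[tr$run_id == run] >= rs & tr$t_ms[tr$run_id == run] <= re))
  }
})

test_that("blink injection is optional, bounded, and time-locked", {
  s0 <- quiet_samples(5000)
  ident <- inject_blinks(s0, blink_rate = 0)
  expect_identical(ident$samples, s0)
  expect_equal(nrow(ident$blinks), 0)

  set.seed(40)
  bl <- inject_blinks(quiet_samples(20000, runs = c("run01", "run02")),
                      blink_rate = 20, seed = 41)
  expect_gt(nrow(bl$blinks), 0)
  # blinks never overlap run boundaries
  for (b in seq_len(nrow(bl$blinks))) {
    idx <- bl$samples$run_id == bl$blinks$run_id[b]
    expect_gte(bl$blinks$start_ms[b], min(bl$samples$t_ms[idx]))
    expect_lte(bl$blinks$end_ms[b], max(bl$samples$t_ms[idx]))
  }
  # the gap is missing in both eyes at the same samples
  expect_identical(is.na(bl$samples$pL), is.na(bl$samples$pR))
  expect_gt(sum(is.na(bl$samples$pL)), 0)
})
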