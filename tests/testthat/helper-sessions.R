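# Small in-code fixtures shared across test files.

# A quiet constant-signal samples frame for one or more runs.
quiet_samples <- function(n = 2000, runs = "run01", pupil = 4.5, gaze = 0,
                          start_ms = 0, gap_ms = 5000) {
  out <- list()
  t0 <- start_ms
  for (run in runs) {
    out[[run]] <- data.frame(run_id = run, t_ms = t0 + seq_len(n) - 1L,
                             xL = gaze, yL = gaze, pL = pupil, validL = TRUE,
                             xR = gaze, yR = gaze, pR = pupil, validR = TRUE,
                             stringsAsFactors = FALSE)
    t0 <- t0 + n + gap_ms
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Events frame from explicit press times (ms) within one run.
make_events <- function(press_ms, run_id = "run01", run_start = 0,
                        run_end = 45000, effector = "hand") {
  data.frame(t_ms = c(run_start, press_ms, run_end), run_id = run_id,
             type = c("run_start", rep("press", length(press_ms)), "run_end"),
             effector = c("none", rep(effector, length(press_ms)), "none"),
             stringsAsFactors = FALSE)
}

# Insert a minimum-jerk saccade of `amp_deg` over `dur` samples into both
# eyes' horizontal gaze, starting at sample index i0.
add_saccade <- function(samples, i0, amp_deg = 0.35, dur = 20) {
  tau <- seq(0, 1, length.out = dur + 1)
  prof <- amp_deg * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  n <- nrow(samples)
  idx <- i0:(i0 + dur)
  for (col in c("xL", "xR")) {
    samples[idx, col] <- samples[idx, col] + prof
    if (i0 + dur < n)
      samples[(i0 + dur + 1):n, col] <- samples[(i0 + dur + 1):n, col] + amp_deg
  }
  samples
}

# Add independent white gaze noise so the velocity threshold is defined.
add_gaze_noise <- function(samples, sd = 0.002, seed = 99) {
  set.seed(seed)
  for (col in c("xL", "yL", "xR", "yR"))
    samples[[col]] <- samples[[col]] + rnorm(nrow(samples), 0, sd)
  samples
}

expect_rate_curve_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$rate, b$rate, tolerance = tol)
  expect_equal(a$denom, b$denom)
}
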