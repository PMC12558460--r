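empty_sacc <- function() data.frame(run_id = character(0), timestamp_ms = numeric(0))

sacc_at <- function(ts_ms, run = "run01")
  data.frame(run_id = run, timestamp_ms = ts_ms, stringsAsFactors = FALSE)

test_that("press merging is chained and annotates intervals and flags", {
  ev <- make_events(c(0, 250, 500) + 10000)
  m <- merge_presses(ev)
  expect_equal(nrow(m), 1)
  expect_equal(m$t_ms, 10000)
  expect_equal(m$n_presses, 3L)
  expect_true(m$first_or_last)

  ev2 <- make_events(c(10000, 10350))
  m2 <- merge_presses(ev2)
  expect_equal(nrow(m2), 2)

  ev3 <- make_events(c(5000, 9000, 10800, 20000))
  m3 <- merge_presses(ev3)
  expect_equal(m3$interval_pre_s, c(NA, 4, 1.8, 9.2))
  expect_equal(m3$interval_post_s, c(4, 1.8, 9.2, NA))
  expect_equal(m3$isolated, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(m3$first_or_last, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("the rate formula divides counts by bin width times effective events", {
  # 40 well-separated events in one long run; 2 saccades in one bin
  press <- 10000 + (0:39) * 6000
  ev <- make_events(press, run_end = 260000)
  events <- merge_presses(ev)
  runs <- run_table(ev)
  sacc <- sacc_at(press[5] + c(505, 515))   # both in bin [0.5, 0.525)
  cur <- event_rate_curve(sacc, events, runs)
  bin <- which(abs(cur$offset_s - 0.5125) < 1e-9)
  expect_equal(cur$rate[bin], 2 / (0.025 * 40))
  expect_equal(cur$denom, rep(40, 220))
  # no saccades -> zero wherever events contribute
  cur0 <- event_rate_curve(empty_sacc(), events, runs)
  expect_true(all(cur0$rate[cur0$denom > 0] == 0))
  expect_error(event_rate_curve(empty_sacc(), events[0, ], runs), "no motor events")
})

test_that("overlap exclusion removes the shared span from both windows", {
  ev <- make_events(c(10000, 14000), run_end = 45000)
  events <- merge_presses(ev)
  runs <- run_table(ev)
  cur <- event_rate_curve(empty_sacc(), events, runs)
  # the absolute span [11.5, 13] s is removed from BOTH windows: offsets
  # [1.5, 3] of the first event and [-2.5, -1] of the second
  first_bad <- cur$offset_s > 1.5 & cur$offset_s < 3
  second_bad <- cur$offset_s > -2.5 & cur$offset_s < -1
  expect_true(all(!cur$valid[1, first_bad]))
  expect_true(all(!cur$valid[2, second_bad]))
  # on the offset axis each excluded bin still has the other event valid
  expect_true(all(cur$denom[first_bad | second_bad] == 1))
  expect_true(all(cur$denom[!(first_bad | second_bad)] == 2))
})

test_that("the rate curve equals a brute-force per-event enumeration", {
  set.seed(70)
  press <- sort(sample(seq(4000, 116000, by = 250), 25))
  ev <- make_events(press, run_end = 120000)
  events <- merge_presses(ev)
  runs <- run_table(ev)
  sacc <- sacc_at(sort(runif(260, 0, 120000)))
  cur <- event_rate_curve(sacc, events, runs)

  # independent oracle: explicit loops over events, bins and neighbors
  edges <- seq(-2500, 3000, by = 25)
  nb <- length(edges) - 1
  counts <- den <- rep(0, nb)
  for (e in events$t_ms) {
    for (b in seq_len(nb)) {
      lo <- e + edges[b]; hi <- e + edges[b + 1]
      ok <- lo >= 0 && hi <= 120000
      for (o in setdiff(events$t_ms, e)) {
        ilo <- max(e - 2500, o - 2500); ihi <- min(e + 3000, o + 3000)
        if (ilo < ihi && lo < ihi && hi > ilo) ok <- FALSE
      }
      if (ok) {
        den[b] <- den[b] + 1
        counts[b] <- counts[b] +
          sum(sacc$timestamp_ms >= lo & sacc$timestamp_ms < hi)
      }
    }
  }
  expect_equal(cur$denom, den)
  expect_equal(cur$rate, ifelse(den > 0, counts / (0.025 * den), NA_real_))

  # baseline: time-weighted rate over the first 500 ms and last 1000 ms
  base_bins <- c(1:20, 181:220)
  expect_equal(cur$baseline,
               sum(counts[base_bins]) / (0.025 * sum(den[base_bins])))
})

test_that("boxcar smoothing matches the stated window and edge rules", {
  press <- 10000 + (0:19) * 6000
  ev <- make_events(press, run_end = 140000)
  events <- merge_presses(ev)
  runs <- run_table(ev)
  set.seed(71)
  sacc <- sacc_at(sort(runif(200, 0, 140000)))
  cur <- event_rate_curve(sacc, events, runs)
  sm <- smooth_rate_curve(cur)

  oracle <- sapply(seq_along(cur$rate), function(b) {
    i <- max(1, b - 5):min(length(cur$rate), b + 4)
    i <- i[cur$denom[i] > 0]
    if (length(i)) mean(cur$rate[i]) else NA_real_
  })
  expect_equal(sm$rate, oracle)

  # a unit impulse spreads as 1/10 over its 10-bin window
  imp <- cur
  imp$rate <- rep(0, 220); imp$rate[100] <- 1; imp$denom <- rep(1, 220)
  smi <- smooth_rate_curve(imp)
  expect_equal(smi$rate[96:105], rep(0.1, 10))
  expect_equal(smi$rate[c(95, 106)], c(0, 0))

  # constant curves are unchanged in the interior
  const <- cur; const$rate <- rep(2, 220); const$denom <- rep(5, 220)
  expect_equal(smooth_rate_curve(const)$rate, rep(2, 220))
  expect_error(smooth_rate_curve(cur, width_ms = 110), "multiple")
})

test_that("per-event metrics divide by each window's own width", {
  ev <- make_events(c(10000, 20000, 26000, 27500))
  events <- merge_presses(ev)

  m0 <- per_event_rate_metric(empty_sacc(), events)
  expect_equal(m0[1], 0)

  m1 <- per_event_rate_metric(sacc_at(10500), events)
  expect_equal(m1[1], 1)          # one saccade at +0.5 s -> 1/1.0

  m2 <- per_event_rate_metric(sacc_at(9600), events)
  expect_equal(m2[1], -1.25)      # one saccade at -0.4 s -> -1/0.8

  # non-isolated events are flagged invalid
  expect_true(all(is.na(m1[3:4])))

  expect_equal(modulation_index(c(1, -1, NA)), 0)
  expect_equal(modulation_index(rep(0.4, 5)), 0.4)
  set.seed(72)
  r <- rnorm(20)
  expect_equal(modulation_index(r), mean(r))
  expect_error(modulation_index(c(NA_real_, NA_real_)), "no valid")
})
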