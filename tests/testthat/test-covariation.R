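test_that("tonic pupil size is the run-restricted windowed mean", {
  n <- 45000
  run <- rep("run01", n)
  t_ms <- seq_len(n) - 1

  expect_equal(tonic_pupil(rep(4.2, n), t_ms, run), rep(4.2, n))

  ramp <- 4 + 1e-5 * t_ms
  tn <- tonic_pupil(ramp, t_ms, run)
  mid <- 22500
  expect_equal(tn[mid], ramp[mid], tolerance = 1e-6)
  # edge windows truncate to within-run samples: oracle check
  expect_equal(tn[1], mean(ramp[1:15001]))
  expect_equal(tn[n], mean(ramp[(n - 15000):n]))
  i <- 2000
  expect_equal(tn[i], mean(ramp[1:(i + 15000)]))

  # missing data are ignored
  ramp2 <- ramp; ramp2[10000:12000] <- NA
  tn2 <- tonic_pupil(ramp2, t_ms, run)
  expect_equal(tn2[11000], mean(ramp2[1:26000], na.rm = TRUE))

  # two runs do not share windows
  run2 <- rep(c("run01", "run02"), each = 5000)
  x <- c(rep(1, 5000), rep(9, 5000))
  tn3 <- tonic_pupil(x, seq_len(10000) - 1, run2)
  expect_equal(tn3, x)
})

test_that("the per-event table applies the stated exclusions", {
  ev <- make_events(c(4000, 9000, 15000, 16500, 24000, 30000))
  events <- merge_presses(ev)
  n <- nrow(events)
  rate_m <- seq_len(n) * 0.1
  pupil_m <- seq_len(n) * 0.01
  t_ms <- 0:44999
  tonic <- rep(4.5, 45000)
  tab <- build_event_table(events, rate_m, pupil_m, tonic, t_ms)
  # first (4000) and last (30000) excluded; 15000/16500 not isolated
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rate_mod, c(0.2, 0.5))
  expect_equal(tab$tonic_pupil, c(4.5, 4.5))
  expect_equal(tab$interval_pre, c(5, 7.5))

  # tonic fallback: nearest non-missing within 1 s
  tonic2 <- tonic; tonic2[8000:9500] <- NA
  tab2 <- build_event_table(events, rate_m, pupil_m, tonic2, t_ms)
  expect_equal(tab2$tonic_pupil[1], 4.5)

  # brute-force enumeration of surviving events on random event sets
  set.seed(100)
  for (rep_ in 1:5) {
    press <- sort(sample(seq(2000, 43000, by = 400), 12))
    evr <- merge_presses(make_events(press))
    m <- rep(1, nrow(evr))
    tabr <- build_event_table(evr, m, m, tonic, t_ms)
    keep <- sapply(seq_along(evr$t_ms), function(j) {
      gaps <- abs(evr$t_ms - evr$t_ms[j])[-j] / 1000
      all(gaps >= 2.5) && j != 1 && j != nrow(evr)
    })
    expect_equal(nrow(tabr), sum(keep))
  }
})

test_that("the standardized regression matches the normal equations", {
  set.seed(101)
  n <- 200
  tab <- data.frame(pupil_mod = rnorm(n), tonic_pupil = rnorm(n),
                    interval_pre = rnorm(n), interval_post = rnorm(n))
  tab$rate_mod <- 0.5 * tab$pupil_mod - 0.3 * tab$interval_pre + rnorm(n, 0, 0.5)
  fit <- fit_participant_regression(tab)
  expect_false(fit$excluded)

  # oracle: z-score (ddof 1) then solve X'X b = X'y directly
  z <- scale(as.matrix(tab[c("rate_mod", "pupil_mod", "tonic_pupil",
                             "interval_pre", "interval_post")]))
  X <- z[, -1]; y <- z[, 1]
  b <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef), unname(drop(b)), tolerance = 1e-10)
  # standardized slope: true b * sd(x)/sd(y); with this noise level sd(y)~0.85
  expect_equal(unname(fit$coef["pupil_mod"]),
               0.5 * sd(tab$pupil_mod) / sd(tab$rate_mod), tolerance = 0.1)

  # identical response and predictor -> coefficient (1, 0, 0, 0)
  tab2 <- tab; tab2$rate_mod <- tab2$pupil_mod
  fit2 <- fit_participant_regression(tab2)
  expect_equal(unname(fit2$coef), c(1, 0, 0, 0), tolerance = 1e-10)

  # fewer than ten events -> excluded flag, not an estimate
  fit3 <- fit_participant_regression(tab[1:9, ])
  expect_true(fit3$excluded)
  expect_true(all(is.na(fit3$coef)))

  # zero-variance column -> error
  tab4 <- tab; tab4$tonic_pupil <- 1
  expect_error(fit_participant_regression(tab4), "zero-variance")
})

test_that("interval-driven amplitudes do not masquerade as saccade-pupil coupling", {
  # amplitudes are a linear function of the preceding interval, with no
  # shared per-event factor: the interval predictors must absorb the
  # association, leaving the pupil coefficient non-significant
  cv <- validate_covariation(n_participants = 12, n_runs = 4,
                             coupling_mode = "interval", seed = 300)
  g <- cv$group
  expect_gt(g$p[g$predictor == "pupil_mod"], 0.01)
})

test_that("the group test matches the t formula and its symmetries", {
  set.seed(102)
  co <- matrix(rnorm(100 * 4, mean = 0.3, sd = 0.1), 100, 4,
               dimnames = list(NULL, c("pupil_mod", "tonic_pupil",
                                       "interval_pre", "interval_post")))
  g <- group_coefficient_test(co)
  x <- co[, 1]
  t_hand <- mean(x) / (sd(x) / sqrt(length(x)))
  expect_equal(g$t[1], t_hand)
  expect_equal(g$df[1], 99)
  expect_equal(g$p[1], 2 * pt(-abs(t_hand), 99))
  expect_equal(g$prop_positive[1], mean(x > 0))

  # sign flip: t flips, p unchanged
  g2 <- group_coefficient_test(-co)
  expect_equal(g2$t, -g$t)
  expect_equal(g2$p, g$p)

  # all-zero coefficients: the zero-variance convention
  g0 <- group_coefficient_test(matrix(0, 5, 2,
                                      dimnames = list(NULL, c("a", "b"))))
  expect_equal(g0$t, c(0, 0))
  expect_equal(g0$p, c(1, 1))

  expect_error(group_coefficient_test(co[1, , drop = FALSE]), ">= 2")
})
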