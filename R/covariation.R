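#' Tonic (slow-varying) pupil size
#'
#' Slides a 30-s boxcar over the preprocessed pupil trace: each sample is
#' assigned the mean of the centered window, restricted to the sample's own
#' run and ignoring missing data. A fully missing window yields `NA`.
#'
#' @param pupil preprocessed pupil trace (mm).
#' @param t_ms,run_id sample times and run labels.
#' @param width_s boxcar width (s).
#' @return Numeric vector of tonic pupil size (mm), aligned with `pupil`.
#' @export
tonic_pupil <- function(pupil, t_ms, run_id, width_s = 30) {
  half <- round(width_s * 1000 / 2)
  out <- rep(NA_real_, length(pupil))
  for (run in unique(run_id)) {
    idx <- which(run_id == run)
    p <- pupil[idx]
    n <- length(p)
    ok <- is.finite(p)
    cs <- cumsum(ifelse(ok, p, 0))
    cn <- cumsum(ok)
    i <- seq_len(n)
    lo <- pmax(1L, i - half)
    hi <- pmin(n, i + half)
    tot <- cs[hi] - c(0, cs)[lo]
    cnt <- cn[hi] - c(0, cn)[lo]
    out[idx] <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  out
}

#' Per-event table for the covariation analysis
#'
#' Joins, for each motor event, the saccade-rate modulation metric, the
#' pupil modulation metric, the inter-event intervals, and the tonic pupil
#' size at the event, then applies the exclusions: events with a neighbor
#' closer than the isolation radius, events that are the first or last of
#' their run, and events with any non-finite column. Tonic pupil size at a
#' missing sample falls back to the nearest non-missing sample within 1 s.
#'
#' @param events motor-event data frame from [merge_presses()].
#' @param rate_metrics,pupil_metrics per-event metric vectors.
#' @param tonic tonic pupil series from [tonic_pupil()].
#' @param t_ms sample times aligned with `tonic`.
#' @return Data frame with columns `rate_mod`, `pupil_mod`, `interval_pre`,
#'   `interval_post`, `tonic_pupil` (one row per retained event), with the
#'   number of excluded events in attribute `n_excluded`.
#' @export
build_event_table <- function(events, rate_metrics, pupil_metrics, tonic, t_ms) {
  tp <- vapply(seq_len(nrow(events)), function(j) {
    i <- which.min(abs(t_ms - events$t_ms[j]))
    if (is.finite(tonic[i])) return(tonic[i])
    win <- which(abs(t_ms - events$t_ms[j]) <= 1000 & is.finite(tonic))
    if (!length(win)) return(NA_real_)
    tonic[win[which.min(abs(t_ms[win] - events$t_ms[j]))]]
  }, numeric(1))
  tab <- data.frame(rate_mod = rate_metrics, pupil_mod = pupil_metrics,
                    interval_pre = events$interval_pre_s,
                    interval_post = events$interval_post_s,
                    tonic_pupil = tp)
  keep <- events$isolated & !events$first_or_last &
    apply(is.finite(as.matrix(tab)), 1, all)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Per-participant standardized covariation regression
#'
#' Z-scores the response (saccade-rate modulation) and the four predictors
#' (pupil modulation, tonic pupil size, preceding and following inter-event
#' interval) using the participant's own sample mean and SD, and fits
#' ordinary least squares without an intercept (z-scoring forces it to 0).
#' Participants with fewer than `min_events` rows are flagged excluded.
#'
#' @param table per-event table from [build_event_table()].
#' @param min_events minimal number of valid events.
#' @return A list: `coef` (named standardized coefficients), `n_events`,
#'   `excluded`.
#' @export
fit_participant_regression <- function(table, min_events = 10) {
  preds <- c("pupil_mod", "tonic_pupil", "interval_pre", "interval_post")
  if (nrow(table) < min_events)
    return(list(coef = stats::setNames(rep(NA_real_, 4), preds),
                n_events = nrow(table), excluded = TRUE))
  sds <- vapply(table[c("rate_mod", preds)], stats::sd, numeric(1))
  if (any(sds == 0)) stop("zero-variance column: cannot z-score")
  z <- as.data.frame(scale(table[c("rate_mod", preds)]))
  fit <- stats::lm(rate_mod ~ 0 + pupil_mod + tonic_pupil + interval_pre +
                     interval_post, data = z)
  list(coef = stats::coef(fit), n_events = nrow(table), excluded = FALSE)
}

#' Across-participant test of the standardized coefficients
#'
#' Compares each predictor's across-participant distribution of standardized
#' coefficients to 0 with a two-tailed one-sample t-test, and reports the
#' descriptives (median, interquartile range, proportion positive).
#'
#' @param coef_matrix participants-by-predictors matrix of coefficients
#'   (excluded participants omitted or `NA` rows dropped).
#' @return Data frame with one row per predictor: `t`, `df`, `p`, `mean`,
#'   `median`, `iqr`, `prop_positive`, `n`.
#' @export
group_coefficient_test <- function(coef_matrix) {
  coef_matrix <- coef_matrix[stats::complete.cases(coef_matrix), , drop = FALSE]
  if (nrow(coef_matrix) < 2) stop("need >= 2 participants for the group test")
  res <- lapply(colnames(coef_matrix), function(pr) {
    x <- coef_matrix[, pr]
    if (stats::sd(x) > 0) {
      tt <- stats::t.test(x, mu = 0)
      tval <- unname(tt$statistic); dfv <- unname(tt$parameter); pval <- tt$p.value
    } else {           # zero-variance convention, as for the pointwise tests
      tval <- 0; dfv <- length(x) - 1; pval <- 1
    }
    data.frame(predictor = pr, t = tval, df = dfv, p = pval,
               mean = mean(x), median = stats::median(x),
               iqr = stats::IQR(x), prop_positive = mean(x > 0),
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
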