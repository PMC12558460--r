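intervals_from_flags <- function(flag, t_ms) {
  r <- rle(flag)
  if (!length(r$values)) return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_ms = t_ms[starts[keep]], end_ms = t_ms[ends[keep]])
}

merge_close_intervals <- function(iv, max_gap) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start_ms), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv$start_ms[i] - out$end_ms[nrow(out)] < max_gap) {
      out$end_ms[nrow(out)] <- max(out$end_ms[nrow(out)], iv$end_ms[i])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Detect blinks from rapid pupil change and signal absence
#'
#' Flags, separately per eye and per run, maximal spans where the absolute
#' pupil change rate exceeds `change_threshold` or the pupil signal is
#' absent; spans separated by less than `merge_gap` are bridged. Candidate
#' spans that overlap between the two eyes are accepted as (binocular)
#' blinks; signal-absence spans that are not part of an accepted blink are
#' returned as a missing-data mask instead.
#'
#' @param samples a samples data frame (see [render_session()]).
#' @param change_threshold pupil change-rate threshold (mm/s).
#' @param merge_gap maximal gap (ms) bridged between candidate spans.
#' @return A list with `blinks` (data frame `run_id`, `start_ms`, `end_ms`,
#'   `binocular`) and `missing` (logical vector along `samples` rows: signal
#'   absence in either eye outside any accepted blink).
#' @export
detect_blinks <- function(samples, change_threshold = 25, merge_gap = 50) {
  stopifnot(change_threshold > 0, merge_gap > 0)
  fs <- 1000
  blinks <- list()
  missing <- rep(FALSE, nrow(samples))
  for (run in unique(samples$run_id)) {
    idx <- which(samples$run_id == run)
    t_ms <- samples$t_ms[idx]
    cand <- list()
    for (eye in c("L", "R")) {
      p <- samples[idx, paste0("p", eye)]
      rate <- c(0, diff(p)) * fs
      flag <- is.na(p) | (!is.na(rate) & abs(rate) > change_threshold)
      iv <- intervals_from_flags(flag, t_ms)
      cand[[eye]] <- merge_close_intervals(iv, merge_gap)
    }
    # binocular verification: keep candidates overlapping between the eyes
    acc <- list()
    if (nrow(cand$L) && nrow(cand$R)) {
      for (i in seq_len(nrow(cand$L))) {
        ov <- cand$R$start_ms <= cand$L$end_ms[i] & cand$R$end_ms >= cand$L$start_ms[i]
        if (any(ov)) {
          acc[[length(acc) + 1]] <- data.frame(
            run_id = run,
            start_ms = min(cand$L$start_ms[i], cand$R$start_ms[ov]),
            end_ms = max(cand$L$end_ms[i], cand$R$end_ms[ov]),
            binocular = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    run_blinks <- if (length(acc)) {
      merged <- merge_close_intervals(do.call(rbind, acc)[, c("start_ms", "end_ms")], 1)
      data.frame(run_id = run, merged, binocular = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(run_id = character(0), start_ms = numeric(0), end_ms = numeric(0),
                 binocular = logical(0), stringsAsFactors = FALSE)
    }
    blinks[[run]] <- run_blinks
    both_na <- is.na(samples$pL[idx]) & is.na(samples$pR[idx])
    in_blink <- rep(FALSE, length(idx))
    for (b in seq_len(nrow(run_blinks)))
      in_blink <- in_blink | (t_ms >= run_blinks$start_ms[b] & t_ms <= run_blinks$end_ms[b])
    any_na <- is.na(samples$pL[idx]) | is.na(samples$pR[idx])
    missing[idx] <- any_na & !in_blink
  }
  blinks <- do.call(rbind, blinks)
  rownames(blinks) <- NULL
  list(blinks = blinks, missing = missing)
}

#' Interpolate blinks in a pupil trace
#'
#' Replaces each blink interval (padded by `pad` ms on each side) with the
#' straight line joining the median pupil size within a `win`-ms window just
#' before the padded interval to the median within a `win`-ms window just
#' after it (medians anchored at the window centers). Blinks abutting a run
#' edge, or with no finite values in a flanking window, are left as missing
#' rather than extrapolated.
#'
#' @param pupil numeric pupil trace (mm), aligned with `t_ms`.
#' @param t_ms,run_id sample times and run labels.
#' @param blinks blink data frame from [detect_blinks()].
#' @param pad padding (ms) added to each side of a blink.
#' @param win width (ms) of the flanking median windows.
#' @return The interpolated pupil trace.
#' @export
interpolate_blinks <- function(pupil, t_ms, run_id, blinks, pad = 20, win = 50) {
  out <- pupil
  for (b in seq_len(nrow(blinks))) {
    run <- blinks$run_id[b]
    idx <- which(run_id == run)
    tt <- t_ms[idx]
    i0 <- which(tt >= blinks$start_ms[b] - pad)[1]
    i1 <- max(which(tt <= blinks$end_ms[b] + pad))
    if (is.na(i0) || is.na(i1)) next
    pre_i <- (i0 - win):(i0 - 1)
    post_i <- (i1 + 1):(i1 + win)
    if (i0 - win < 1 || i1 + win > length(idx)) {
      out[idx[max(1, i0):min(length(idx), i1)]] <- NA_real_
      next
    }
    med_pre <- stats::median(out[idx[pre_i]], na.rm = TRUE)
    med_post <- stats::median(out[idx[post_i]], na.rm = TRUE)
    if (!is.finite(med_pre) || !is.finite(med_post)) {
      out[idx[i0:i1]] <- NA_real_
      next
    }
    # anchor the medians at the centers of their windows
    x0 <- mean(pre_i)
    x1 <- mean(post_i)
    out[idx[i0:i1]] <- med_pre + (med_post - med_pre) * ((i0:i1) - x0) / (x1 - x0)
  }
  out
}

#' Pupil change-rate signal
#'
#' Differences the pupil trace between consecutive samples, scales to mm/s,
#' and low-pass filters the derivative with a zero-phase (forward-backward)
#' third-order Butterworth filter with a 25-Hz critical frequency. Filtering
#' is applied per run; missing samples are linearly bridged for the filter
#' pass and restored to `NA` afterwards.
#'
#' @param pupil pupil trace (mm) at `fs` Hz, blink-interpolated.
#' @param run_id run labels aligned with `pupil` (a single run when `NULL`).
#' @param fs sampling rate (Hz).
#' @param cutoff_hz filter critical frequency (Hz).
#' @return Change-rate signal (mm/s), `NA` where the source was missing.
#' @export
pupil_change_rate <- function(pupil, run_id = NULL, fs = 1000, cutoff_hz = 25) {
  if (is.null(run_id)) run_id <- rep("run01", length(pupil))
  bf <- signal::butter(3, cutoff_hz / (fs / 2), type = "low")
  out <- rep(NA_real_, length(pupil))
  for (run in unique(run_id)) {
    idx <- which(run_id == run)
    p <- pupil[idx]
    n <- length(p)
    if (n < 100) stop("run shorter than filter warm-up (need >= 100 samples)")
    v <- c(NA_real_, diff(p)) * fs
    v[1] <- v[2]
    nas <- !is.finite(v)
    if (all(nas)) next
    if (any(nas)) {
      fi <- which(!nas)
      v <- stats::approx(fi, v[fi], xout = seq_len(n), rule = 2)$y
    }
    vf <- signal::filtfilt(bf, v)
    vf[nas & !is.finite(c(NA, p[-n])) & !is.finite(p)] <- NA_real_
    vf[!is.finite(p)] <- NA_real_
    out[idx] <- vf
  }
  out
}

#' Preprocess a session's pupil signals
#'
#' Runs the full pupillometry preprocessing chain: blink detection
#' ([detect_blinks()]), the mean-of-eyes pupil trace (falling back to the
#' valid eye when only one eye has signal), blink interpolation
#' ([interpolate_blinks()]), and the low-pass-filtered change-rate signal
#' ([pupil_change_rate()]).
#'
#' @param samples a samples data frame.
#' @param change_threshold,merge_gap see [detect_blinks()].
#' @param pad,win see [interpolate_blinks()].
#' @return A list: `pupil` (interpolated mean-of-eyes trace, mm),
#'   `change_rate` (mm/s), `blinks`, `missing`, `t_ms`, `run_id`.
#' @export
preprocess_session <- function(samples, change_threshold = 25, merge_gap = 50,
                               pad = 20, win = 50) {
  det <- detect_blinks(samples, change_threshold, merge_gap)
  # mean of eyes, falling back to the valid eye during monocular dropouts
  pm <- rowMeans(cbind(samples$pL, samples$pR), na.rm = TRUE)
  pm[is.nan(pm)] <- NA_real_
  pm <- interpolate_blinks(pm, samples$t_ms, samples$run_id, det$blinks,
                           pad = pad, win = win)
  cr <- pupil_change_rate(pm, samples$run_id)
  list(pupil = pm, change_rate = cr, blinks = det$blinks,
       missing = det$missing, t_ms = samples$t_ms, run_id = samples$run_id)
}
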