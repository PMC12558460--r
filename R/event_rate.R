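#' Merge closely spaced presses into motor events
#'
#' Collapses chains of raw presses less than `gap_ms` apart (each press
#' compared to the previous raw press) into a single motor event timestamped
#' at the first press of the chain, then annotates each motor event with the
#' intervals to its neighboring motor events, an isolation flag (no neighbor
#' closer than `isolation_s`), and whether it is the first or last event of
#' its run.
#'
#' @param events an events data frame containing `press` rows.
#' @param gap_ms merge threshold (ms) between consecutive raw presses.
#' @param isolation_s isolation radius (s).
#' @return Data frame of motor events: `t_ms`, `run_id`, `effector`,
#'   `n_presses`, `interval_pre_s`, `interval_post_s`, `isolated`,
#'   `first_or_last`.
#' @export
merge_presses <- function(events, gap_ms = 300, isolation_s = 2.5) {
  presses <- events[events$type == "press", , drop = FALSE]
  out <- list()
  for (run in unique(presses$run_id)) {
    p <- presses[presses$run_id == run, , drop = FALSE]
    p <- p[order(p$t_ms), , drop = FALSE]
    if (!nrow(p)) next
    grp <- cumsum(c(TRUE, diff(p$t_ms) >= gap_ms))
    t_ev <- tapply(p$t_ms, grp, function(x) x[1])
    n_pr <- tapply(p$t_ms, grp, length)
    ne <- length(t_ev)
    iv_pre <- c(NA, diff(t_ev)) / 1000
    iv_post <- c(diff(t_ev), NA) / 1000
    isolated <- (is.na(iv_pre) | iv_pre >= isolation_s) &
      (is.na(iv_post) | iv_post >= isolation_s)
    out[[run]] <- data.frame(t_ms = as.numeric(t_ev), run_id = run,
                             effector = p$effector[1],
                             n_presses = as.integer(n_pr),
                             interval_pre_s = iv_pre, interval_post_s = iv_post,
                             isolated = isolated,
                             first_or_last = seq_len(ne) %in% c(1L, ne),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(t_ms = numeric(0), run_id = character(0),
                      effector = character(0), n_presses = integer(0),
                      interval_pre_s = numeric(0), interval_post_s = numeric(0),
                      isolated = logical(0), first_or_last = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-event bin validity: a bin is invalid if its absolute interval overlaps
# the intersection of this event's peri-event window with a neighboring
# event's window (the overlap is removed from BOTH windows), or extends
# beyond the run.
event_bin_validity <- function(ev_ms, run_start, run_end, neighbors_ms,
                               edges_ms) {
  lo <- ev_ms + edges_ms[-length(edges_ms)]
  hi <- ev_ms + edges_ms[-1]
  valid <- lo >= run_start & hi <= run_end
  w0 <- edges_ms[1]
  w1 <- edges_ms[length(edges_ms)]
  for (nb in neighbors_ms) {
    int_lo <- max(ev_ms + w0, nb + w0)
    int_hi <- min(ev_ms + w1, nb + w1)
    if (int_lo < int_hi)
      valid <- valid & !(lo < int_hi & hi > int_lo)
  }
  valid
}

#' Event-locked saccade-rate curve
#'
#' Tallies saccades (by their midpoint timestamp, each assigned to exactly
#' one 25-ms bin) in a peri-event window around every motor event, and
#' estimates the rate per bin as the total count divided by the bin width
#' times the number of events validly contributing to that bin. A bin of a
#' given event is excluded (from count and denominator alike) when its
#' absolute time span overlaps a neighboring event's peri-event window --
#' the overlap is removed from both windows -- or extends beyond the run.
#' The baseline is the time-weighted rate over the first 500 ms and last
#' 1000 ms of the window.
#'
#' @param saccades saccade data frame (needs `timestamp_ms`, `run_id`).
#' @param events motor-event data frame from [merge_presses()].
#' @param runs run table from [run_table()].
#' @param window peri-event window (s).
#' @param bin_s bin width (s).
#' @return An object of class `rate_curve`: list with `offset_s` (bin
#'   centers), `rate` (saccades/s, `NA` where no event contributes), `denom`
#'   (effective event count per bin), `baseline`, `n_events`, and the
#'   per-event `counts`/`valid` matrices.
#' @export
event_rate_curve <- function(saccades, events, runs, window = c(-2.5, 3),
                             bin_s = 0.025) {
  if (!nrow(events)) stop("no motor events: cannot form a rate curve")
  edges_s <- seq(window[1], window[2], by = bin_s)
  edges_ms <- edges_s * 1000
  nb <- length(edges_s) - 1
  ne <- nrow(events)
  valid <- matrix(FALSE, ne, nb)
  counts <- matrix(0L, ne, nb)
  for (j in seq_len(ne)) {
    run <- events$run_id[j]
    ri <- match(run, runs$run_id)
    nbrs <- events$t_ms[events$run_id == run & seq_len(ne) != j]
    nbrs <- nbrs[abs(nbrs - events$t_ms[j]) < (window[2] - window[1]) * 1000]
    valid[j, ] <- event_bin_validity(events$t_ms[j], runs$start_ms[ri],
                                     runs$end_ms[ri], nbrs, edges_ms)
    st <- saccades$timestamp_ms[saccades$run_id == run]
    off <- st - events$t_ms[j]
    off <- off[off >= edges_ms[1] & off < edges_ms[length(edges_ms)]]
    if (length(off)) {
      bins <- floor((off - edges_ms[1]) / (bin_s * 1000)) + 1L
      tb <- tabulate(bins, nbins = nb)
      counts[j, ] <- ifelse(valid[j, ], tb, 0L)
    }
  }
  denom <- colSums(valid)
  rate <- ifelse(denom > 0, colSums(counts) / (bin_s * denom), NA_real_)
  base_idx <- which(edges_s[-1] <= window[1] + 0.5 |
                      edges_s[-length(edges_s)] >= window[2] - 1.0)
  bd <- sum(valid[, base_idx])
  baseline <- if (bd > 0) sum(counts[, base_idx]) / (bin_s * bd) else NA_real_
  structure(list(offset_s = (edges_s[-1] + edges_s[-length(edges_s)]) / 2,
                 rate = rate, denom = denom, baseline = baseline,
                 n_events = ne, counts = counts, valid = valid,
                 bin_s = bin_s, window = window, smoothed = FALSE),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat("<rate_curve>", length(x$rate), "bins of", x$bin_s * 1000, "ms over [",
      x$window[1], ",", x$window[2], "] s;", x$n_events, "events; baseline",
      signif(x$baseline, 4), "saccades/s",
      if (x$smoothed) "(smoothed)" else "", "\n")
  invisible(x)
}

#' Boxcar-smooth a rate curve
#'
#' Sliding 250-ms boxcar on the 25-ms grid: bin `b` is replaced by the mean
#' over bins `b-5 .. b+4` (exact 250-ms width with half-bin asymmetry),
#' excluding bins with a zero denominator; edges use the available bins only.
#'
#' @param curve a `rate_curve`.
#' @param width_ms boxcar width (ms), a multiple of the bin size.
#' @return The smoothed `rate_curve`.
#' @export
smooth_rate_curve <- function(curve, width_ms = 250) {
  bw <- curve$bin_s * 1000
  if (width_ms %% bw != 0) stop("width must be a multiple of the bin size")
  k <- width_ms / bw
  back <- floor(k / 2)
  fwd <- k - back - 1
  nb <- length(curve$rate)
  sm <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    i <- max(1, b - back):min(nb, b + fwd)
    i <- i[curve$denom[i] > 0]
    if (length(i)) sm[b] <- mean(curve$rate[i])
  }
  curve$rate <- sm
  curve$smoothed <- TRUE
  curve
}

#' Per-event saccade-rate modulation metric
#'
#' For each isolated motor event, the saccade rate tallied in the post-event
#' rebound window minus the rate in the pre-event suppression window, each
#' count divided by its own window's width. Positive values indicate more
#' saccades after than before the event. Non-isolated events get `NA`.
#'
#' @param saccades saccade data frame.
#' @param events motor-event data frame from [merge_presses()].
#' @param pre,post metric windows (s, relative to the event).
#' @return Numeric vector (saccades/s), one value per event row.
#' @export
per_event_rate_metric <- function(saccades, events, pre = c(-0.8, 0),
                                  post = c(0.2, 1.2)) {
  st <- sort(saccades$timestamp_ms)
  count_in <- function(lo, hi)
    findInterval(hi - 1e-9, st) - findInterval(lo - 1e-9, st)
  vapply(seq_len(nrow(events)), function(j) {
    if (!events$isolated[j]) return(NA_real_)
    e <- events$t_ms[j]
    count_in(e + post[1] * 1000, e + post[2] * 1000) / (post[2] - post[1]) -
      count_in(e + pre[1] * 1000, e + pre[2] * 1000) / (pre[2] - pre[1])
  }, numeric(1))
}

#' Participant-level saccade modulation index
#'
#' Mean of the per-event rate-modulation metrics across a participant's
#' valid (isolated) motor events.
#'
#' @param metrics vector from [per_event_rate_metric()].
#' @return A single value (saccades/s).
#' @export
modulation_index <- function(metrics) {
  m <- metrics[is.finite(metrics)]
  if (!length(m)) stop("no valid motor events for the modulation index")
  mean(m)
}
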