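#' Five-point moving-window velocity
#'
#' Computes the gaze velocity `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) /
#' (6 dt)`, which is exact for linear motion and suppresses sample-to-sample
#' noise relative to a two-point difference. The first and last two samples
#' are `NA`.
#'
#' @param x position series (deg).
#' @param dt sample interval (s).
#' @return Velocity series (deg/s), same length as `x`.
#' @export
velocity_trace <- function(x, dt) {
  n <- length(x)
  if (n < 5) stop("run too short for the 5-point velocity window (need >= 5 samples)")
  v <- rep(NA_real_, n)
  v[3:(n - 2)] <- (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) / (6 * dt)
  v
}

#' Median-based robust velocity scale
#'
#' The detector's scale estimator `sigma^2 = median(v^2) - median(v)^2`,
#' robust to the saccades themselves. Note that for Gaussian noise this
#' estimator converges to about 0.6745 times the standard deviation (the
#' square root of the chi-square median), which is the convention the
#' velocity-threshold detector is calibrated for.
#'
#' @param v velocity series (deg/s), `NA`s ignored.
#' @return The robust scale (deg/s), or `NA` for a degenerate trace.
#' @export
robust_velocity_sd <- function(v) {
  s2 <- stats::median(v^2, na.rm = TRUE) - stats::median(v, na.rm = TRUE)^2
  if (!is.finite(s2) || s2 <= 0) return(NA_real_)
  sqrt(s2)
}

#' Monocular saccade candidates by velocity thresholding
#'
#' Marks periods where the two-dimensional gaze velocity deviates strongly
#' from the norm: per-component thresholds `eta = lambda * sigma` use the
#' median-based scale estimator `sigma^2 = median(v^2) - median(v)^2`
#' (computed per run), and a candidate is a maximal span where
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` lasting at least `min_dur_ms`.
#'
#' @param vx,vy component velocity series (deg/s).
#' @param t_ms sample times (ms).
#' @param lambda threshold multiplier (unitless).
#' @param min_dur_ms minimum candidate span (ms).
#' @return Data frame of candidate periods (`start_ms`, `end_ms`). A trace
#'   with (numerically) zero velocity variance yields no candidates, with a
#'   warning.
#' @export
detect_monocular <- function(vx, vy, t_ms, lambda = 6, min_dur_ms = 6) {
  stopifnot(lambda > 0, length(vx) == length(vy), length(vx) == length(t_ms))
  ex <- lambda * robust_velocity_sd(vx)
  ey <- lambda * robust_velocity_sd(vy)
  if (!is.finite(ex) || !is.finite(ey) || ex == 0 || ey == 0) {
    warning("velocity threshold undefined (zero-variance trace); run skipped")
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  }
  crit <- (vx / ex)^2 + (vy / ey)^2 > 1
  crit[is.na(crit)] <- FALSE
  iv <- intervals_from_flags(crit, t_ms)
  iv[iv$end_ms - iv$start_ms + 1 >= min_dur_ms, , drop = FALSE]
}

#' Merge binocular candidates and apply retention rules
#'
#' Pools the candidate periods from both eyes of one run, merges periods
#' separated by `merge_gap_ms` or less into one candidate, labels a merged
#' candidate binocular iff it contains contributions from both eyes, and then
#' retains only candidates that are binocular, have a duration inside
#' `dur_range_ms`, and lie farther than `blink_margin_ms` from every detected
#' blink. Amplitude and direction are taken from the displacement of the
#' mean-of-eyes gaze between the candidate's first and last sample, and the
#' timestamp is the midpoint of start and end.
#'
#' @param candL,candR candidate data frames from [detect_monocular()].
#' @param blinks blink data frame (may have zero rows).
#' @param t_ms sample times (ms) for the run.
#' @param gx,gy mean-of-eyes gaze components (deg), aligned with `t_ms`.
#' @param vx,vy mean-of-eyes velocity components (deg/s) for peak velocity.
#' @param merge_gap_ms,blink_margin_ms,dur_range_ms rule parameters.
#' @return Data frame of retained saccades: `start_ms`, `end_ms`,
#'   `timestamp_ms`, `amplitude_arcmin`, `direction_deg`, `peak_velocity`,
#'   `binocular`.
#' @export
merge_and_filter <- function(candL, candR, blinks, t_ms, gx, gy,
                             vx = NULL, vy = NULL,
                             merge_gap_ms = 5, blink_margin_ms = 10,
                             dur_range_ms = c(8, 200)) {
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      timestamp_ms = numeric(0), amplitude_arcmin = numeric(0),
                      direction_deg = numeric(0), peak_velocity = numeric(0),
                      binocular = logical(0))
  pool <- rbind(
    if (nrow(candL)) cbind(candL, eye = "L") else NULL,
    if (nrow(candR)) cbind(candR, eye = "R") else NULL)
  if (is.null(pool) || !nrow(pool)) return(empty)
  pool <- pool[order(pool$start_ms), , drop = FALSE]
  groups <- list()
  cur <- pool[1, , drop = FALSE]
  cur_end <- cur$end_ms
  for (i in seq_len(nrow(pool))[-1]) {
    if (pool$start_ms[i] - cur_end <= merge_gap_ms) {
      cur <- rbind(cur, pool[i, , drop = FALSE])
      cur_end <- max(cur_end, pool$end_ms[i])
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- pool[i, , drop = FALSE]
      cur_end <- cur$end_ms
    }
  }
  groups[[length(groups) + 1]] <- cur

  out <- lapply(groups, function(g) {
    s <- min(g$start_ms); e <- max(g$end_ms)
    data.frame(start_ms = s, end_ms = e, timestamp_ms = (s + e) / 2,
               binocular = length(unique(g$eye)) == 2)
  })
  out <- do.call(rbind, out)

  dur <- out$end_ms - out$start_ms
  keep <- out$binocular & dur >= dur_range_ms[1] & dur <= dur_range_ms[2]
  if (nrow(blinks)) {
    for (b in seq_len(nrow(blinks))) {
      near <- out$start_ms <= blinks$end_ms[b] + blink_margin_ms &
        out$end_ms >= blinks$start_ms[b] - blink_margin_ms
      keep <- keep & !near
    }
  }
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) return(empty)

  i0 <- findInterval(out$start_ms, t_ms)
  i1 <- findInterval(out$end_ms, t_ms)
  dx <- gx[i1] - gx[i0]
  dy <- gy[i1] - gy[i0]
  out$amplitude_arcmin <- 60 * sqrt(dx^2 + dy^2)
  out$direction_deg <- atan2(dy, dx) * 180 / pi
  out$peak_velocity <- NA_real_
  if (!is.null(vx)) {
    for (i in seq_len(nrow(out))) {
      sp <- i0[i]:i1[i]
      out$peak_velocity[i] <- max(sqrt(vx[sp]^2 + vy[sp]^2), na.rm = TRUE)
    }
  }
  rownames(out) <- NULL
  out[, c("start_ms", "end_ms", "timestamp_ms", "amplitude_arcmin",
          "direction_deg", "peak_velocity", "binocular")]
}

#' Detect fixational saccades in a session
#'
#' Applies the binocular velocity-threshold detector run by run:
#' [velocity_trace()] per eye and component, [detect_monocular()] per eye,
#' then [merge_and_filter()] with the session's blinks.
#'
#' @param samples a samples data frame.
#' @param blinks blink data frame from [detect_blinks()] (optional).
#' @param lambda velocity threshold multiplier.
#' @param min_dur_ms minimum candidate span (ms).
#' @return Data frame of retained saccades with a `run_id` column.
#' @export
detect_saccades <- function(samples, blinks = NULL, lambda = 6, min_dur_ms = 6) {
  if (is.null(blinks))
    blinks <- data.frame(run_id = character(0), start_ms = numeric(0),
                         end_ms = numeric(0))
  out <- list()
  for (run in unique(samples$run_id)) {
    idx <- which(samples$run_id == run)
    t_ms <- samples$t_ms[idx]
    dt <- 1e-3 * diff(t_ms[1:2])
    vxL <- velocity_trace(samples$xL[idx], dt); vyL <- velocity_trace(samples$yL[idx], dt)
    vxR <- velocity_trace(samples$xR[idx], dt); vyR <- velocity_trace(samples$yR[idx], dt)
    candL <- detect_monocular(vxL, vyL, t_ms, lambda, min_dur_ms)
    candR <- detect_monocular(vxR, vyR, t_ms, lambda, min_dur_ms)
    gx <- rowMeans(cbind(samples$xL[idx], samples$xR[idx]), na.rm = TRUE)
    gy <- rowMeans(cbind(samples$yL[idx], samples$yR[idx]), na.rm = TRUE)
    sac <- merge_and_filter(candL, candR,
                            blinks[blinks$run_id == run, , drop = FALSE],
                            t_ms, gx, gy,
                            vx = (vxL + vxR) / 2, vy = (vyL + vyR) / 2)
    if (nrow(sac)) out[[run]] <- cbind(run_id = run, sac)
  }
  if (!length(out))
    return(data.frame(run_id = character(0), start_ms = numeric(0),
                      end_ms = numeric(0), timestamp_ms = numeric(0),
                      amplitude_arcmin = numeric(0), direction_deg = numeric(0),
                      peak_velocity = numeric(0), binocular = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
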