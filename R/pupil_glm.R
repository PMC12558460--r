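#' Downsample a 1-kHz signal to the deconvolution frame grid
#'
#' Averages the signal within consecutive 1/30-s frames, separately per run;
#' frames containing only missing samples are `NA`.
#'
#' @param x signal at 1 kHz (e.g. the pupil change rate, mm/s).
#' @param t_ms,run_id sample times and run labels.
#' @param runs run table from [run_table()].
#' @param frame_rate frame rate (Hz).
#' @return Data frame of frames: `run_id`, `frame` (0-based index within
#'   run), `t_ms` (frame center), `value`.
#' @export
downsample_frames <- function(x, t_ms, run_id, runs, frame_rate = 30) {
  out <- list()
  for (r in seq_len(nrow(runs))) {
    run <- runs$run_id[r]
    idx <- which(run_id == run)
    if (!length(idx)) next
    rel <- t_ms[idx] - runs$start_ms[r]
    f <- floor(rel * frame_rate / 1000)
    v <- tapply(x[idx], f, function(z) {
      z <- z[is.finite(z)]
      if (length(z)) mean(z) else NA_real_
    })
    fr <- as.integer(names(v))
    out[[run]] <- data.frame(run_id = run, frame = fr,
                             t_ms = runs$start_ms[r] + (fr + 0.5) * 1000 / frame_rate,
                             value = as.numeric(v), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Staggered-impulse (FIR) design matrix
#'
#' Builds the deconvolution design: for each event type, one column per
#' 1/30-s offset within that type's window, with a 1 at the frame containing
#' `event time + offset` for every event of that type (columns of a set are
#' staggered like a Toeplitz matrix). Placements falling outside the event's
#' run are dropped.
#'
#' @param events events data frame (`t_ms`, `run_id`, `type`).
#' @param windows named list mapping event type to its window `c(start, end)`
#'   in seconds relative to the event.
#' @param frames frame grid from [downsample_frames()].
#' @param runs run table.
#' @param frame_rate frame rate (Hz).
#' @return Design matrix (frames x total kernel length) with attributes
#'   `type` and `offset_s` describing each column.
#' @export
build_design <- function(events, windows, frames, runs, frame_rate = 30) {
  if (!nrow(frames)) stop("empty frame grid")
  key <- paste(frames$run_id, frames$frame)
  cols_type <- character(0)
  cols_off <- numeric(0)
  blocks <- list()
  for (type in names(windows)) {
    w <- windows[[type]]
    K <- floor((w[2] - w[1]) * frame_rate)
    offs <- w[1] + (0:K) / frame_rate
    X <- matrix(0, nrow(frames), K + 1)
    ev <- events[events$type == type, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      ri <- match(ev$run_id[j], runs$run_id)
      if (is.na(ri)) next
      tgt <- ev$t_ms[j] / 1000 + offs
      fi <- floor((tgt - runs$start_ms[ri] / 1000) * frame_rate)
      row <- match(paste(ev$run_id[j], fi), key)
      ok <- !is.na(row)
      if (any(ok))
        X[cbind(row[ok], which(ok))] <- X[cbind(row[ok], which(ok))] + 1
    }
    blocks[[type]] <- X
    cols_type <- c(cols_type, rep(type, K + 1))
    cols_off <- c(cols_off, offs)
  }
  X <- do.call(cbind, blocks)
  attr(X, "type") <- cols_type
  attr(X, "offset_s") <- cols_off
  X
}

#' Fit the deconvolution model by ridge regression
#'
#' Solves the FIR model with an L2 penalty chosen from `penalty_grid` by
#' efficient (closed-form) leave-one-out cross-validation on the frames,
#' after dropping frames with a missing response and centering both sides
#' (the intercept is recovered from the means). Coefficients are partitioned
#' back into one kernel per event type.
#'
#' @param X design matrix from [build_design()].
#' @param y response at the frame grid (mm/s), `NA` frames are dropped.
#' @param penalty_grid candidate ridge penalties.
#' @return A list: `kernels` (named list of data frames `offset_s`,
#'   `value`), `penalty` (selected), `loo_error` (per candidate),
#'   `intercept`.
#' @export
fit_deconvolution <- function(X, y, penalty_grid = c(0.1, 1, 10)) {
  keep <- is.finite(y)
  if (!any(keep)) stop("all frames missing: cannot fit the deconvolution model")
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  xm <- colMeans(Xk)
  ym <- mean(yk)
  Xc <- sweep(Xk, 2, xm)
  yc <- yk - ym
  sv <- svd(Xc)
  uty <- drop(crossprod(sv$u, yc))
  U2 <- sv$u^2
  loo <- vapply(penalty_grid, function(lam) {
    w <- sv$d^2 / (sv$d^2 + lam)
    fit <- drop(sv$u %*% (w * uty))
    h <- drop(U2 %*% w)
    mean(((yc - fit) / pmax(1 - h, 1e-10))^2)
  }, numeric(1))
  lam <- penalty_grid[which.min(loo)]
  beta <- drop(sv$v %*% ((sv$d / (sv$d^2 + lam)) * uty))
  types <- attr(X, "type")
  offs <- attr(X, "offset_s")
  kernels <- lapply(split(seq_along(beta), types), function(i)
    data.frame(offset_s = offs[i], value = beta[i]))
  structure(list(kernels = kernels, penalty = lam,
                 loo_error = stats::setNames(loo, penalty_grid),
                 intercept = ym - sum(xm * beta)),
            class = "pupil_deconvolution")
}

#' @export
print.pupil_deconvolution <- function(x, ...) {
  cat("<pupil_deconvolution> kernels:",
      paste(sprintf("%s (%d pts)", names(x$kernels),
                    vapply(x$kernels, nrow, integer(1))), collapse = ", "),
      "; ridge penalty", x$penalty, "\n")
  invisible(x)
}

#' Naive event-locked average kernel
#'
#' The comparison estimator for the deconvolution: the plain average of the
#' frame-grid response at each offset across events, with no account of
#' overlapping responses.
#'
#' @inheritParams build_design
#' @param type event type to average.
#' @param window window (s) relative to the event.
#' @return Data frame `offset_s`, `value`.
#' @export
naive_event_average <- function(events, type, window, frames, runs,
                                frame_rate = 30) {
  K <- floor((window[2] - window[1]) * frame_rate)
  offs <- window[1] + (0:K) / frame_rate
  key <- paste(frames$run_id, frames$frame)
  ev <- events[events$type == type, , drop = FALSE]
  acc <- matrix(NA_real_, nrow(ev), K + 1)
  for (j in seq_len(nrow(ev))) {
    ri <- match(ev$run_id[j], runs$run_id)
    tgt <- ev$t_ms[j] / 1000 + offs
    fi <- floor((tgt - runs$start_ms[ri] / 1000) * frame_rate)
    row <- match(paste(ev$run_id[j], fi), key)
    acc[j, !is.na(row)] <- frames$value[row[!is.na(row)]]
  }
  data.frame(offset_s = offs, value = colMeans(acc, na.rm = TRUE))
}

#' Integrate a change-rate kernel to a size curve
#'
#' Riemann-sum integration of a pupil change-rate kernel: the cumulative sum
#' of values times the 1/30-s frame spacing, with the value at the window
#' start fixed at 0 (pupil size relative to the start of the window).
#'
#' @param kernel data frame `offset_s`, `value` (mm/s).
#' @param frame_rate frame rate (Hz).
#' @return The kernel data frame with an added `integrated` column (mm).
#' @export
integrate_kernel <- function(kernel, frame_rate = 30) {
  v <- kernel$value
  kernel$integrated <- c(0, cumsum(v)[-length(v)]) / frame_rate
  kernel
}

#' Per-event pupil modulation metric
#'
#' For each isolated motor event, the mean pupil change rate in the
#' pre-event dilation window minus the mean in the post-event re-constriction
#' window, read from the 1-kHz change-rate signal. Positive values indicate
#' stronger dilation-then-constriction modulation. Non-isolated events get
#' `NA`.
#'
#' @param change_rate change-rate signal (mm/s) at 1 kHz.
#' @param t_ms sample times aligned with `change_rate`.
#' @param events motor-event data frame from [merge_presses()].
#' @param dilation,constriction metric windows (s, relative to the event).
#' @return Numeric vector (mm/s), one value per event row.
#' @export
per_event_pupil_metric <- function(change_rate, t_ms, events,
                                   dilation = c(-0.6, 0.2),
                                   constriction = c(0.6, 1.6)) {
  win_mean <- function(e, w) {
    i0 <- findInterval(e + w[1] * 1000 - 1e-9, t_ms) + 1L
    i1 <- findInterval(e + w[2] * 1000 - 1e-9, t_ms)
    if (i1 < i0) return(NA_real_)
    mean(change_rate[i0:i1], na.rm = TRUE)
  }
  vapply(seq_len(nrow(events)), function(j) {
    if (!events$isolated[j]) return(NA_real_)
    win_mean(events$t_ms[j], dilation) - win_mean(events$t_ms[j], constriction)
  }, numeric(1))
}

#' Fit the press-locked pupil deconvolution for one session
#'
#' Convenience wrapper: downsamples the change-rate signal to 30 Hz, builds
#' the staggered design for presses plus the selected nuisance event types,
#' and fits the ridge deconvolution.
#'
#' @param pre preprocessed session from [preprocess_session()].
#' @param events events data frame.
#' @param saccades detected saccades (needed for the oculomotor nuisance
#'   variant).
#' @param nuisance `"runstart"` (run-start regressors only, the primary
#'   model) or `"runstart+oculomotor"` (additionally blink and saccade
#'   regressors).
#' @param press_window,runstart_window,blink_window,saccade_window kernel
#'   windows (s).
#' @param penalty_grid ridge penalties.
#' @return A `pupil_deconvolution` (see [fit_deconvolution()]).
#' @export
fit_session_deconvolution <- function(pre, events, saccades = NULL,
                                      nuisance = c("runstart", "runstart+oculomotor"),
                                      press_window = c(-2, 5.5),
                                      runstart_window = c(0, 5.5),
                                      blink_window = c(0, 4),
                                      saccade_window = c(0, 2),
                                      penalty_grid = c(0.1, 1, 10)) {
  nuisance <- match.arg(nuisance)
  runs <- run_table(events)
  frames <- downsample_frames(pre$change_rate, pre$t_ms, pre$run_id, runs)
  ev <- events
  windows <- list(press = press_window, run_start = runstart_window)
  if (nuisance == "runstart+oculomotor") {
    extra <- list()
    if (!is.null(pre$blinks) && nrow(pre$blinks))
      extra$blink <- data.frame(t_ms = pre$blinks$start_ms,
                                run_id = pre$blinks$run_id, type = "blink",
                                effector = "none", stringsAsFactors = FALSE)
    if (!is.null(saccades) && nrow(saccades))
      extra$saccade <- data.frame(t_ms = saccades$timestamp_ms,
                                  run_id = saccades$run_id, type = "saccade",
                                  effector = "none", stringsAsFactors = FALSE)
    ev <- rbind(ev[, c("t_ms", "run_id", "type", "effector")],
                do.call(rbind, extra))
    windows$blink <- blink_window
    windows$saccade <- saccade_window
  }
  X <- build_design(ev, windows, frames, runs)
  fit_deconvolution(X, frames$value, penalty_grid)
}
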