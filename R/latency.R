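#' Locate a curve extremum inside a search window
#'
#' Returns the offset of the minimum or maximum value within the window;
#' ties are broken toward the earliest offset. A warning flag notes extrema
#' that sit on the window boundary (possible truncation).
#'
#' @param offsets timepoint offsets (s).
#' @param values curve values aligned with `offsets`.
#' @param window search window `c(lo, hi)` (s).
#' @param kind `"min"` or `"max"`.
#' @return A list: `offset` (s), `value`, `on_boundary`.
#' @export
curve_extremum <- function(offsets, values, window, kind = c("min", "max")) {
  kind <- match.arg(kind)
  sel <- which(offsets >= window[1] & offsets <= window[2] & is.finite(values))
  if (!length(sel)) stop("empty extremum search window")
  i <- if (kind == "min") sel[which.min(values[sel])] else sel[which.max(values[sel])]
  list(offset = offsets[i], value = values[i],
       on_boundary = i == sel[1] || i == sel[length(sel)])
}

#' Lags between saccade-rate and pupil change-rate modulations
#'
#' Quantifies the temporal lag between the event-locked fixational saccade
#' rate curve and the event-locked pupil change-rate kernel: the pre-event
#' lag is the latency from the rate minimum (just before the event) to the
#' pupil change-rate peak around that time; the post-event lag is the
#' latency from the first rate peak after the event to the first pupil
#' change-rate minimum after it. Computed on across-participant average
#' curves.
#'
#' @param rate_offsets,rate_values the (smoothed) saccade-rate curve.
#' @param pupil_offsets,pupil_values the press-locked pupil change-rate
#'   kernel.
#' @param windows named list of search windows (s): `rate_min`,
#'   `pupil_peak`, `rate_peak`, `pupil_min`.
#' @return A list: `pre_lag_ms`, `post_lag_ms`, the four extremum locations,
#'   and `truncated` (TRUE when any extremum sat on a window boundary).
#' @export
modulation_lag <- function(rate_offsets, rate_values, pupil_offsets, pupil_values,
                           windows = list(rate_min = c(-1, 0.2),
                                          pupil_peak = c(-1, 0.5),
                                          rate_peak = c(0, 1.2),
                                          pupil_min = c(0, 2))) {
  rmin <- curve_extremum(rate_offsets, rate_values, windows$rate_min, "min")
  ppeak <- curve_extremum(pupil_offsets, pupil_values, windows$pupil_peak, "max")
  rpeak <- curve_extremum(rate_offsets, rate_values, windows$rate_peak, "max")
  pmin <- curve_extremum(pupil_offsets, pupil_values, windows$pupil_min, "min")
  truncated <- rmin$on_boundary || ppeak$on_boundary || rpeak$on_boundary ||
    pmin$on_boundary
  if (truncated)
    warning("an extremum lies on its search-window boundary (possible truncation)")
  list(pre_lag_ms = (ppeak$offset - rmin$offset) * 1000,
       post_lag_ms = (pmin$offset - rpeak$offset) * 1000,
       rate_min_s = rmin$offset, pupil_peak_s = ppeak$offset,
       rate_peak_s = rpeak$offset, pupil_min_s = pmin$offset,
       truncated = truncated)
}

#' Pupil light reflex latency
#'
#' The delay between a luminance increment and the subsequent minimum of the
#' pupil change rate (the moment of most rapid constriction), read from the
#' luminance-increment kernel of the light-reflex deconvolution.
#'
#' @param kernel data frame `offset_s`, `value` for the `lum_increment`
#'   event type.
#' @param window search window (s) after light onset.
#' @return Latency in ms (grid-quantized at the kernel's frame spacing).
#' @export
plr_latency <- function(kernel, window = c(0, 1.5)) {
  sel <- which(kernel$offset_s >= window[1] & kernel$offset_s <= window[2] &
                 is.finite(kernel$value))
  if (!length(sel)) stop("empty search window for the light-reflex latency")
  i <- sel[which.min(kernel$value[sel])]
  if (i == sel[1] || i == sel[length(sel)])
    stop("no interior change-rate minimum: kernel monotone over the window")
  kernel$offset_s[i] * 1000
}
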