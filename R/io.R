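SAMPLES_DIALECT <- "# fixpupil-samples v1"
EVENTS_DIALECT <- "# fixpupil-events v1"
SAMPLE_COLS <- c("run_id", "t_ms", "xL", "yL", "pL", "validL",
                 "xR", "yR", "pR", "validR")
EVENT_COLS <- c("t_ms", "run_id", "type", "effector")
EVENT_TYPES <- c("press", "run_start", "run_end", "lum_increment", "lum_decrement")

parse_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fixpupil_parse_error", "error")))
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)   # lossless round-trip for doubles
  out[is.na(x)] <- "NA"
  out
}

#' Write a session to disk
#'
#' Serializes a session in the package's plain-text dialect: samples as a
#' tab-separated file and events as a comma-separated file, each opened by a
#' dialect-version header line. Missing values are encoded as the literal
#' token `NA`; numeric columns use a lossless decimal representation, so
#' output bytes are deterministic and a read/write cycle is the identity.
#'
#' @param samples,events data frames as produced by [render_session()].
#' @param samples_path,events_path output file paths.
#' @return Invisibly, the two paths.
#' @seealso [read_session()]
#' @export
write_session <- function(samples, events, samples_path, events_path) {
  stopifnot(all(SAMPLE_COLS %in% names(samples)),
            all(EVENT_COLS %in% names(events)))
  s_lines <- c(SAMPLES_DIALECT,
               paste(SAMPLE_COLS, collapse = "\t"))
  if (nrow(samples)) {
    body <- paste(samples$run_id, samples$t_ms,
                  fmt_num(samples$xL), fmt_num(samples$yL), fmt_num(samples$pL),
                  ifelse(samples$validL, "TRUE", "FALSE"),
                  fmt_num(samples$xR), fmt_num(samples$yR), fmt_num(samples$pR),
                  ifelse(samples$validR, "TRUE", "FALSE"),
                  sep = "\t")
    s_lines <- c(s_lines, body)
  }
  writeLines(s_lines, samples_path)
  e_lines <- c(EVENTS_DIALECT, paste(EVENT_COLS, collapse = ","))
  if (nrow(events)) {
    e_lines <- c(e_lines, paste(events$t_ms, events$run_id, events$type,
                                events$effector, sep = ","))
  }
  writeLines(e_lines, events_path)
  invisible(c(samples_path, events_path))
}

#' Read a session from disk
#'
#' Parses the samples-TSV and events-CSV dialects written by
#' [write_session()], validating the dialect headers, the uniform 1-ms time
#' grid within each run, event types, and that every press lies within its
#' run. Violations raise typed conditions of class `fixpupil_parse_error`.
#'
#' @param samples_path,events_path input file paths.
#' @return A list with `samples` and `events` data frames.
#' @export
read_session <- function(samples_path, events_path) {
  if (!file.exists(samples_path) || !file.exists(events_path))
    parse_error("session file not found", "fixpupil_missing_file")
  h1 <- readLines(samples_path, n = 1)
  if (!identical(h1, SAMPLES_DIALECT))
    parse_error(sprintf("malformed samples header: %s", h1), "fixpupil_bad_header")
  samples <- utils::read.table(samples_path, sep = "\t", skip = 1, header = TRUE,
                               colClasses = c(run_id = "character", t_ms = "integer",
                                              xL = "numeric", yL = "numeric",
                                              pL = "numeric", validL = "logical",
                                              xR = "numeric", yR = "numeric",
                                              pR = "numeric", validR = "logical"),
                               na.strings = "NA", stringsAsFactors = FALSE)
  if (!identical(names(samples), SAMPLE_COLS))
    parse_error("samples columns do not match dialect", "fixpupil_bad_header")

  h2 <- readLines(events_path, n = 1)
  if (!identical(h2, EVENTS_DIALECT))
    parse_error(sprintf("malformed events header: %s", h2), "fixpupil_bad_header")
  events <- utils::read.table(events_path, sep = ",", skip = 1, header = TRUE,
                              colClasses = c(t_ms = "integer", run_id = "character",
                                             type = "character", effector = "character"),
                              stringsAsFactors = FALSE)
  if (!identical(names(events), EVENT_COLS))
    parse_error("events columns do not match dialect", "fixpupil_bad_header")

  validate_session(samples, events)
  list(samples = samples, events = events)
}

validate_session <- function(samples, events) {
  for (run in unique(samples$run_id)) {
    tt <- samples$t_ms[samples$run_id == run]
    if (length(tt) > 1 && !all(diff(tt) == diff(tt)[1] & diff(tt) > 0))
      parse_error(sprintf("non-uniform time grid in %s", run),
                  "fixpupil_nonuniform_grid")
  }
  if (nrow(events)) {
    bad <- !events$type %in% EVENT_TYPES
    if (any(bad))
      parse_error(sprintf("unknown event type: %s", events$type[bad][1]),
                  "fixpupil_bad_event_type")
    runs <- run_table(events)
    presses <- events[events$type == "press", , drop = FALSE]
    if (nrow(presses)) {
      i <- match(presses$run_id, runs$run_id)
      out <- is.na(i) | presses$t_ms < runs$start_ms[i] | presses$t_ms > runs$end_ms[i]
      if (any(out))
        parse_error("press outside its run interval", "fixpupil_press_outside_run")
    }
  }
  invisible(TRUE)
}

#' Run boundaries from an event log
#'
#' @param events an events data frame containing `run_start`/`run_end` rows.
#' @return Data frame with `run_id`, `start_ms`, `end_ms`.
#' @export
run_table <- function(events) {
  st <- events[events$type == "run_start", ]
  en <- events[events$type == "run_end", ]
  rt <- data.frame(run_id = st$run_id, start_ms = st$t_ms,
                   end_ms = en$t_ms[match(st$run_id, en$run_id)],
                   stringsAsFactors = FALSE)
  rt[order(rt$start_ms), , drop = FALSE]
}
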