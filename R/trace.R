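#' Uniformly sampled time-series trace with event annotations
#'
#' The common carrier for all one-dimensional assays: calcium transients and
#' cell length (time in ms), fluorometric and oxygen traces (time in s).
#' Events (stimuli, reagent additions) live in a side table rather than being
#' inferred from the signal, so analyzers stay honest about what is given.
#'
#' @param time numeric vector, strictly increasing, uniformly spaced.
#' @param value numeric vector, same length as `time`.
#' @param events data.frame with columns `time`, `label` and optionally
#'   `amount`; may be empty.
#' @param time_unit "ms" or "s"; informational.
#' @return An object of class `trace`: a data.frame with columns `time`,
#'   `value` and attributes `events` and `time_unit`.
#' @export
trace <- function(time, value, events = empty_events(), time_unit = "ms") {
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) < 2L) stop("a trace needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("trace time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt))) {
    stop("trace must be uniformly sampled (relative tolerance 1e-9)")
  }
  if (!is.data.frame(events)) stop("events must be a data.frame")
  if (!all(c("time", "label") %in% names(events))) {
    stop("events needs columns time, label")
  }
  if (!"amount" %in% names(events)) events$amount <- rep(NA_real_, nrow(events))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  attr(out, "events") <- events
  attr(out, "time_unit") <- time_unit
  class(out) <- c("trace", "data.frame")
  out
}

#' @export
empty_events <- function() {
  data.frame(time = numeric(0), label = character(0), amount = numeric(0),
             stringsAsFactors = FALSE)
}

#' Event table of a trace
#' @param x a `trace`
#' @return data.frame of events (time, label, amount)
#' @export
trace_events <- function(x) attr(x, "events")

#' Sampling interval of a trace
#' @param x a `trace`
#' @return scalar sampling interval in the trace's time unit
#' @export
trace_dt <- function(x) (x$time[length(x$time)] - x$time[1]) / (nrow(x) - 1L)

#' @export
print.trace <- function(x, ...) {
  ev <- trace_events(x)
  cat(sprintf("<trace> %d samples, dt = %g %s, span [%g, %g], %d events\n",
              nrow(x), trace_dt(x), attr(x, "time_unit"),
              x$time[1], x$time[nrow(x)], nrow(ev)))
  if (nrow(ev) > 0) {
    tab <- table(ev$label)
    cat("  events:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# full-precision numeric formatting so CSV round-trips are lossless
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trace (and its events) to CSV
#'
#' Numeric columns are written with 17 significant digits so that reading the
#' files back reproduces the doubles bit-for-bit.
#'
#' @param x a `trace`
#' @param path CSV path for the samples (columns time, value)
#' @param events_path CSV path for the events; default `<path>` with an
#'   `_events.csv` suffix. Skipped when there are no events and the default
#'   path is used.
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(x, path, events_path = default_events_path(path)) {
  df <- data.frame(time = .fmt_num(x$time), value = .fmt_num(x$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ev <- trace_events(x)
  if (nrow(ev) > 0 || !missing(events_path)) {
    evd <- data.frame(time = .fmt_num(ev$time), label = ev$label,
                      amount = .fmt_num(ev$amount))
    utils::write.csv(evd, events_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

default_events_path <- function(path) {
  sub("\\.csv$", "_events.csv", path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path samples CSV (columns time, value)
#' @param events_path events CSV; read if the file exists
#' @param time_unit passed to [trace()]
#' @return a `trace`
#' @export
read_trace_csv <- function(path, events_path = default_events_path(path),
                           time_unit = "ms") {
  df <- utils::read.csv(path)
  ev <- empty_events()
  if (file.exists(events_path)) {
    raw <- utils::read.csv(events_path, colClasses = c("numeric", "character", "numeric"))
    if (nrow(raw) > 0) ev <- raw
  }
  trace(df$time, df$value, events = ev, time_unit = time_unit)
}
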