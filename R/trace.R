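#' Sampled single-channel current trace
#'
#' Container for a raw current recording sampled at a fixed interval.
#'
#' @param current Numeric vector of currents in pA (finite, length >= 1).
#' @param tau Sampling interval in ms, > 0 (5 kHz sampling gives 0.2 ms).
#' @param meta Optional named list of metadata (condition label, holding
#'   potential, ...).
#' @return Object of class `"trace_record"`.
#' @export
trace_record <- function(current, tau, meta = list()) {
  current <- as.numeric(current)
  if (length(current) < 1L || any(!is.finite(current))) {
    stop("'current' must be a non-empty finite numeric vector (pA)",
         call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a single positive sampling interval (ms)",
         call. = FALSE)
  }
  structure(list(current = current, tau = tau, meta = meta),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("Current trace: %d samples, tau = %g ms (%.4g s total)\n",
              length(x$current), x$tau, length(x$current) * x$tau / 1000))
  invisible(x)
}

#' Read a current trace from delimited text
#'
#' Accepts either a two-column file (time in seconds, current in pA) or a
#' single current column together with an explicit `tau`.  The delimiter
#' (comma, tab or whitespace) is autodetected.  With a time column, the
#' sampling interval is taken as the median time step and the column must be
#' strictly increasing and regular to within 1%.  Vendor binary acquisition
#' formats are not supported; export to plain text first.
#'
#' @param path Path to a delimited text file.
#' @param tau Sampling interval in ms; required when the file has a single
#'   column, ignored (with a check) otherwise.
#' @param meta Optional metadata list, stored on the record.
#' @return A [trace_record()].
#' @export
read_trace <- function(path, tau = NULL, meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = "auto", data.table = FALSE)
    ),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L) stop("format error: empty trace file", call. = FALSE)
  num <- vapply(dt, is.numeric, TRUE)
  if (!all(num)) stop("format error: non-numeric columns in trace file",
                      call. = FALSE)
  if (ncol(dt) == 1L) {
    if (is.null(tau)) {
      stop("format error: single-column trace requires an explicit 'tau'",
           call. = FALSE)
    }
    return(trace_record(dt[[1L]], tau, meta))
  }
  if (ncol(dt) != 2L) {
    stop("format error: expected 1 or 2 columns, got ", ncol(dt),
         call. = FALSE)
  }
  tm <- dt[[1L]]
  if (length(tm) < 2L) stop("format error: need >= 2 samples to infer tau",
                            call. = FALSE)
  steps <- diff(tm)
  if (any(steps <= 0)) {
    stop("format error: time column is not strictly increasing",
         call. = FALSE)
  }
  med <- median(steps)
  if (max(abs(steps - med)) > 0.01 * med) {
    stop("format error: sampling interval varies by more than 1%",
         call. = FALSE)
  }
  tau_ms <- med * 1000  # time column is in seconds
  if (!is.null(tau) && abs(tau - tau_ms) > 0.01 * tau_ms) {
    stop("declared tau (", tau, " ms) disagrees with time column (",
         signif(tau_ms, 6), " ms)", call. = FALSE)
  }
  trace_record(dt[[2L]], tau_ms, meta)
}

#' Idealization thresholds
#'
#' Current-magnitude thresholds classifying each sample: class `"O"` when
#' `|I| >= open_mag`, `"C"` when `|I| <= closed_mag`, `"O_S"` otherwise.
#' Only magnitudes enter, so the classification is invariant to the sign of
#' the recording.
#'
#' @param open_mag Magnitude (pA) at or above which a sample is fully open.
#' @param closed_mag Magnitude (pA) at or below which a sample is closed;
#'   `open_mag > closed_mag > 0`.
#' @return Object of class `"threshold_spec"`.
#' @export
threshold_spec <- function(open_mag, closed_mag) {
  if (!is.numeric(open_mag) || !is.numeric(closed_mag) ||
      length(open_mag) != 1L || length(closed_mag) != 1L ||
      !is.finite(open_mag) || !is.finite(closed_mag) ||
      !(open_mag > closed_mag) || !(closed_mag > 0)) {
    stop("need open_mag > closed_mag > 0 (pA magnitudes)", call. = FALSE)
  }
  structure(list(open_mag = open_mag, closed_mag = closed_mag),
            class = "threshold_spec")
}

#' Run-length-encoded event sequence
#'
#' Sequence of conductance-class events at a fixed sampling interval,
#' stored as maximal runs.  Adjacent runs of the same class are merged by
#' the constructor.
#'
#' @param classes Character vector of per-run classes in
#'   `c("O", "O_S", "C")`.
#' @param lengths Integer vector of run lengths in samples (>= 1).
#' @param tau Sampling interval in ms.
#' @return Object of class `"event_sequence"` with fields `classes`,
#'   `lengths`, `tau` and `n` (total samples).
#' @export
event_sequence <- function(classes, lengths, tau) {
  classes <- as.character(classes)
  lengths <- as.numeric(lengths)
  if (length(classes) != length(lengths) || length(classes) == 0L) {
    stop("'classes' and 'lengths' must be non-empty and equal length",
         call. = FALSE)
  }
  if (!all(classes %in% .classes)) {
    stop("classes must be in {O, O_S, C}", call. = FALSE)
  }
  if (any(lengths < 1) || any(lengths != floor(lengths))) {
    stop("run lengths must be positive integers", call. = FALSE)
  }
  # merge adjacent runs of equal class
  if (length(classes) > 1L) {
    new_run <- c(TRUE, classes[-1L] != classes[-length(classes)])
    grp <- cumsum(new_run)
    lengths <- as.numeric(tapply(lengths, grp, sum))
    classes <- classes[new_run]
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a single positive sampling interval (ms)",
         call. = FALSE)
  }
  structure(list(classes = classes, lengths = lengths, tau = tau,
                 n = sum(lengths)),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("Event sequence: %d runs, %d samples, tau = %g ms\n",
              length(x$classes), x$n, x$tau))
  print(event_counts(x))
  invisible(x)
}

# per-sample class vector (use with care on long sequences)
expand_classes <- function(seq) rep(seq$classes, seq$lengths)

#' Idealize a current trace into conductance-class events
#'
#' Threshold idealization: each sample is classified as fully open when its
#' current magnitude is at least `thr$open_mag`, closed when at most
#' `thr$closed_mag`, and sub-conductance otherwise, then run-length encoded.
#' No filtering is applied by default (set `median_window` to an odd value
#' > 1 for an optional median prefilter).
#'
#' @param trace A [trace_record()].
#' @param thr A [threshold_spec()].
#' @param median_window Odd integer; 1 (default) disables the prefilter.
#' @return An [event_sequence()].
#' @export
idealize <- function(trace, thr, median_window = 1L) {
  stopifnot(inherits(trace, "trace_record"),
            inherits(thr, "threshold_spec"))
  x <- abs(trace$current)
  if (median_window > 1L) {
    x <- stats::runmed(x, k = as.integer(median_window), endrule = "keep")
  }
  cls <- ifelse(x >= thr$open_mag, "O",
                ifelse(x <= thr$closed_mag, "C", "O_S"))
  r <- rle(cls)
  event_sequence(r$values, r$lengths, trace$tau)
}

#' Event and sample counts per conductance class
#'
#' Number of events (maximal runs) and total samples per class; the event
#' counts are the eta scaling factors used when overlaying theoretical
#' dwell-time densities on empirical histograms.
#'
#' @param seq An [event_sequence()].
#' @return data.frame with columns `class`, `n_events`, `n_samples`,
#'   one row per class (all three classes always present).
#' @export
event_counts <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  ev <- vapply(.classes, function(cl) sum(seq$classes == cl), 0)
  ns <- vapply(.classes, function(cl) sum(seq$lengths[seq$classes == cl]), 0)
  data.frame(class = .classes, n_events = as.integer(ev),
             n_samples = ns, row.names = NULL)
}

#' Write an idealized event sequence as a delimited table
#'
#' Writes columns `class`, `start_sample` (1-based), `length` as
#' tab-separated text.
#'
#' @param seq An [event_sequence()].
#' @param path Output file path.
#' @export
write_events <- function(seq, path) {
  stopifnot(inherits(seq, "event_sequence"))
  starts <- cumsum(c(1, head(seq$lengths, -1L)))
  df <- data.frame(class = seq$classes, start_sample = starts,
                   length = seq$lengths)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Input file path.
#' @param tau Sampling interval in ms.
#' @return An [event_sequence()].
#' @export
read_events <- function(path, tau) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  event_sequence(df$class, df$length, tau)
}
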