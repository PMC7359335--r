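#' Extract per-ROI delta-F/F traces
#'
#' ROI trace = mean over member pixels of the raw movie; delta-F/F uses a
#' robust baseline F0 = 8th percentile of the raw ROI trace, which tolerates
#' response transients of either sign. Invariant to multiplicative gain of
#' the movie.
#'
#' @param movie `scan_field_movie`
#' @param mask `roi_mask` aligned to the movie grid
#' @return `roi_trace_set`: list with `traces` (ROI x time), `time_s`,
#'   `rate_hz`, `roi_table`
#' @export
extract_dff <- function(movie, mask) {
  px <- movie$pixels
  d <- dim(px)
  labels <- if (inherits(mask, "roi_mask")) mask$labels else mask
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("mask contains no ROIs")
  flat <- matrix(px, d[1] * d[2], d[3])
  traces <- t(vapply(ids, function(id) {
    idx <- which(labels == id)
    if (!length(idx)) stop("empty ROI: ", id)
    raw <- if (length(idx) == 1) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
    f0 <- stats::quantile(raw, 0.08, names = FALSE)
    if (f0 == 0) stop("zero baseline fluorescence in ROI ", id)
    (raw - f0) / f0
  }, numeric(d[3])))
  structure(list(traces = traces,
                 time_s = (seq_len(d[3]) - 0.5) / movie$rate_hz,
                 rate_hz = movie$rate_hz,
                 roi_table = if (inherits(mask, "roi_mask")) mask$roi_table else NULL),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d ROIs x %d samples @ %g Hz\n",
              nrow(x$traces), ncol(x$traces), x$rate_hz))
  invisible(x)
}

#' Preprocess ROI traces: align, resample, detrend
#'
#' Shifts each ROI's time base by its scan-line sub-frame offset, resamples
#' to 500 Hz by linear interpolation, and detrends with a zero-phase
#' 2nd-order Butterworth high-pass at 0.1 Hz. Zero-phase filtering avoids
#' latency bias in downstream kernels. The sub-frame offset reflects
#' line-sequential scanning: offset_ms = (centroid row / n_rows) * frame
#' period.
#'
#' @param trace_set `roi_trace_set` (or plain matrix with `rate_hz` given)
#' @param trigger_times_s stimulus triggers; all must lie in the recording
#' @param line_offsets_ms per-ROI sub-frame offsets (ms); default 0
#' @param target_rate_hz resampling rate (default 500)
#' @param highpass_hz detrending cutoff (default 0.1)
#' @param rate_hz input rate when `trace_set` is a bare matrix
#' @return new `roi_trace_set` at `target_rate_hz`, detrended, NaN-free
#' @export
preprocess_traces <- function(trace_set, trigger_times_s = numeric(0),
                              line_offsets_ms = 0, target_rate_hz = 500,
                              highpass_hz = 0.1, rate_hz = NULL) {
  if (inherits(trace_set, "roi_trace_set")) {
    traces <- trace_set$traces
    rate_hz <- trace_set$rate_hz
    time_s <- trace_set$time_s
    roi_table <- trace_set$roi_table
  } else {
    traces <- if (is.matrix(trace_set)) trace_set else matrix(trace_set, nrow = 1)
    stopifnot(!is.null(rate_hz))
    time_s <- (seq_len(ncol(traces)) - 0.5) / rate_hz
    roi_table <- NULL
  }
  dur <- ncol(traces) / rate_hz
  if (length(trigger_times_s) && any(trigger_times_s < 0 | trigger_times_s > dur))
    stop("trigger(s) outside recording: ",
         paste(trigger_times_s[trigger_times_s < 0 | trigger_times_s > dur],
               collapse = ", "))
  offsets <- rep_len(line_offsets_ms, nrow(traces)) / 1000
  new_time <- seq(0, dur - 1 / target_rate_hz, by = 1 / target_rate_hz)
  bf <- signal::butter(2, highpass_hz / (target_rate_hz / 2), type = "high")
  out <- t(vapply(seq_len(nrow(traces)), function(i) {
    y <- stats::approx(time_s + offsets[i], traces[i, ], xout = new_time,
                       rule = 2)$y
    as.numeric(signal::filtfilt(bf, y))
  }, numeric(length(new_time))))
  structure(list(traces = out, time_s = new_time, rate_hz = target_rate_hz,
                 roi_table = roi_table,
                 meta = list(highpass_hz = highpass_hz,
                             filter = "zero-phase Butterworth order 2")),
            class = "roi_trace_set")
}

#' Trial-wise response matrix and pointwise median
#'
#' Cuts a trace into equal-length per-repetition segments at the triggers of
#' one condition and returns the pointwise median response plus the T x R
#' repetition matrix (the input of the trial signal-to-noise quality index).
#'
#' @param trace numeric trace (single ROI)
#' @param rate_hz trace sample rate
#' @param trial_table data.frame (condition, t_on, t_off, rep)
#' @param condition condition name to extract
#' @param window_s optional c(start, end) relative to trigger; defaults to
#'   the full trial
#' @return list(median_trace, C = T x R matrix, time_s)
#' @export
trial_median <- function(trace, rate_hz, trial_table, condition,
                         window_s = NULL) {
  rows <- trial_table[trial_table$condition == condition, , drop = FALSE]
  if (nrow(rows) < 1) stop("no repetitions of condition ", condition)
  if (is.null(window_s)) window_s <- c(0, min(rows$t_off - rows$t_on))
  i0 <- round(window_s[1] * rate_hz)
  i1 <- round(window_s[2] * rate_hz) - 1L
  C <- vapply(seq_len(nrow(rows)), function(r) {
    start <- round(rows$t_on[r] * rate_hz)
    idx <- start + i0:i1 + 1L
    if (idx[length(idx)] > length(trace) || idx[1] < 1)
      stop("repetition extends outside the recording")
    trace[idx]
  }, numeric(i1 - i0 + 1L))
  list(median_trace = apply(C, 1, stats::median),
       C = C,
       time_s = (i0:i1 + 0.5) / rate_hz)
}
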