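#' Robust noise estimate of a trace
#'
#' sigma = median(|r(t)|) / 0.6745. For a zero-mean Gaussian trace this
#' equals its standard deviation, because the median absolute value of a
#' standard normal is 0.6745.
#'
#' @param trace numeric, non-empty and finite
#' @export
robust_sigma <- function(trace) {
  if (!length(trace)) stop("empty trace")
  if (!all(is.finite(trace))) stop("trace contains non-finite values")
  stats::median(abs(trace)) / 0.6745
}

#' Detect release/calcium events in a trace
#'
#' Differentiates the trace (first difference times the sample rate),
#' estimates the response threshold as the robust sigma of the derivative,
#' and takes local maxima of the derivative exceeding that threshold as
#' events, weighted by the derivative amplitude. Events are signal
#' increases (positive derivative); plateaus (runs of equal derivative, as
#' produced by resampling) count once, at their earliest sample.
#'
#' @param trace preprocessed trace
#' @param rate_hz sample rate of the trace
#' @return `event_set`: list with `times_s`, `weights` (derivative
#'   amplitude, trace units per s), `indices` (derivative sample index),
#'   `sigma`
#' @export
detect_events <- function(trace, rate_hz) {
  d <- diff(trace) * rate_hz
  if (!length(d))
    return(structure(list(times_s = numeric(0), weights = numeric(0),
                          indices = integer(0), sigma = 0),
                     class = "event_set"))
  sigma <- robust_sigma(d)
  r <- rle(d)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  nruns <- length(v)
  is_max <- rep(FALSE, nruns)
  if (nruns >= 3)
    is_max[2:(nruns - 1)] <- v[2:(nruns - 1)] > v[1:(nruns - 2)] &
      v[2:(nruns - 1)] > v[3:nruns]
  keep <- is_max & v > sigma
  idx <- starts[keep]
  structure(list(times_s = idx / rate_hz, weights = v[keep],
                 indices = idx, sigma = sigma),
            class = "event_set")
}

#' Event-triggered stimulus kernels
#'
#' For each stimulus condition, the event-triggered average stimulus
#' F(tau) = (1/M) * sum_i c(t_i) * S(t_i + tau), where c(t_i) is the event
#' weight and M the event count. Computed on the stimulus time base over a
#' lag window tau in [-lag_window_s, 0]; the divisor is the event count, so
#' kernel amplitude carries the weight units and is meaningful relatively,
#' not absolutely. Events whose lag window extends before the stimulus
#' onset are dropped.
#'
#' @param events `event_set` from [detect_events()]
#' @param protocol stimulus protocol providing S per condition
#' @param lag_window_s lag window length (s); default 2 suits 10 Hz flicker,
#'   1 suits 5 Hz
#' @return `kernel_set`: list with `kernels` (lags x conditions matrix),
#'   `lag_s` (<= 0), `n_events` (M), `empty` flag
#' @export
event_triggered_kernels <- function(events, protocol, lag_window_s = 2) {
  n_lags <- round(lag_window_s * protocol$rate_hz) + 1L
  lag_s <- -rev(seq_len(n_lags) - 1L) / protocol$rate_hz
  cond <- colnames(protocol$channels)
  usable <- events$times_s > lag_window_s &
    events$times_s <= protocol$duration_s
  t_i <- events$times_s[usable]
  c_i <- events$weights[usable]
  M <- length(t_i)
  if (M == 0) {
    return(structure(list(kernels = matrix(NA_real_, n_lags, length(cond),
                                           dimnames = list(NULL, cond)),
                          lag_s = lag_s, n_events = 0L, empty = TRUE),
                     class = "kernel_set"))
  }
  # stimulus sample index for every (event, lag) pair
  idx <- outer(t_i, lag_s, `+`)
  idx <- pmin(pmax(floor(idx * protocol$rate_hz) + 1L, 1L),
              nrow(protocol$channels))
  kernels <- vapply(cond, function(ci) {
    snip <- matrix(protocol$channels[idx, ci], nrow = M)
    colSums(c_i * snip) / M
  }, numeric(n_lags))
  structure(list(kernels = kernels, lag_s = lag_s, n_events = M,
                 empty = FALSE),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("<kernel_set> %d conditions x %d lags, M = %d events\n",
              ncol(x$kernels), nrow(x$kernels), x$n_events))
  invisible(x)
}

#' Stimulus-triggered event kernels for full-field steps
#'
#' Finds full-field light increments (onsets) and decrements (offsets) per
#' color in the protocol and averages the response snippet around each,
#' from 0.1 s before to `post_s` after the step, baseline-subtracted by the
#' mean of the pre-step 0.1 s. These onset/offset event kernels are the
#' input of the full-field opponency measure.
#'
#' @param trace preprocessed response trace
#' @param rate_hz trace sample rate
#' @param protocol protocol containing `uv_fullfield` / `green_fullfield`
#'   channels
#' @param pre_s,post_s snippet window around the step (s)
#' @return nested list `[[color]][[phase]]` with `kernel`, `time_s`
#'   (relative to the step), `n`; a phase with no steps is NULL
#' @export
fullfield_event_kernels <- function(trace, rate_hz, protocol,
                                    pre_s = 0.1, post_s = 1) {
  colors <- c(uv = "uv_fullfield", green = "green_fullfield")
  if (!all(colors %in% colnames(protocol$channels)))
    stop("protocol lacks full-field channels for both colors")
  n_pre <- round(pre_s * rate_hz)
  n_post <- round(post_s * rate_hz)
  rel_idx <- -(n_pre - 1L):n_post
  time_s <- rel_idx / rate_hz
  out <- list()
  for (col in names(colors)) {
    s <- protocol$channels[, colors[[col]]]
    step <- diff(s)
    step_times <- list(onset = which(step > 0) / protocol$rate_hz,
                       offset = which(step < 0) / protocol$rate_hz)
    out[[col]] <- lapply(step_times, function(tt) {
      if (!length(tt)) return(NULL)
      snips <- vapply(tt, function(t0) {
        i0 <- round(t0 * rate_hz)
        idx <- i0 + rel_idx
        if (idx[1] < 1 || idx[length(idx)] > length(trace))
          return(rep(NA_real_, length(rel_idx)))
        trace[idx]
      }, numeric(length(rel_idx)))
      snips <- snips[, stats::complete.cases(t(snips)), drop = FALSE]
      if (!ncol(snips)) return(NULL)
      k <- rowMeans(snips)
      k <- k - mean(k[seq_len(n_pre)])
      list(kernel = k, time_s = time_s, n = ncol(snips))
    })
  }
  out
}
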