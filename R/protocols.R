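#' Stimulus protocols
#'
#' A `stimulus_protocol` bundles the channel-resolved stimulus time courses
#' (UV/green x center/surround, plus full-field channels for flash protocols)
#' with its update rate, trigger times and trial table. Channel intensities
#' are in arbitrary photoisomerization-rate units: 0/1 for flashes, +/-1 for
#' binary flicker.
#'
#' @param kind stimulus kind string
#' @param channels numeric matrix, time steps x conditions (named columns)
#' @param rate_hz stimulus update rate (Hz)
#' @param trigger_times_s repetition onset times (s), strictly increasing
#' @param trial_table data.frame with columns condition, t_on, t_off, rep
#'   (may be NULL for single-sweep stimuli)
#' @param meta list of stimulus geometry metadata
#' @return object of class `stimulus_protocol`
#' @keywords internal
new_stimulus_protocol <- function(kind, channels, rate_hz, trigger_times_s,
                                  trial_table = NULL, meta = list()) {
  stopifnot(is.matrix(channels), rate_hz > 0)
  duration_s <- nrow(channels) / rate_hz
  if (length(trigger_times_s)) {
    if (any(diff(trigger_times_s) <= 0))
      stop("trigger_times_s must be strictly increasing")
    if (any(trigger_times_s < 0 | trigger_times_s > duration_s))
      stop("trigger_times_s must lie within [0, duration_s]")
  }
  structure(
    list(kind = kind, channels = channels, rate_hz = rate_hz,
         trigger_times_s = trigger_times_s, duration_s = duration_s,
         trial_table = trial_table, meta = meta),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s: %d conditions x %d steps @ %g Hz (%.1f s), %d triggers\n",
              x$kind, ncol(x$channels), nrow(x$channels), x$rate_hz,
              x$duration_s, length(x$trigger_times_s)))
  invisible(x)
}

#' Balanced binary center-surround flicker
#'
#' Generates the chromatic flicker used for receptive-field mapping: four
#' independent binary (+/-1) sequences (UV/green x center/surround), each an
#' exactly balanced shuffle of half-high/half-low steps, updated at
#' `rate_hz`. The 10 Hz / 180 s variant is used for bipolar-cell terminals,
#' the 5 Hz / 300 s variant for ganglion-cell-layer somata.
#'
#' @param n_conditions number of independent channels (default 4)
#' @param rate_hz update rate in Hz (default 10)
#' @param duration_s sequence duration in s (default 180)
#' @param seed integer seed; identical seeds give identical sequences
#' @param center_diam_um center spot diameter, metadata only
#' @return a [new_stimulus_protocol()] object with +/-1 channels
#' @examples
#' p <- make_flicker_protocol(seed = 1)
#' colMeans(p$channels)   # exactly 0 for every channel
#' @export
make_flicker_protocol <- function(n_conditions = 4, rate_hz = 10,
                                  duration_s = 180, seed = 1,
                                  center_diam_um = 100) {
  n_steps <- rate_hz * duration_s
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration_s * rate_hz must be an integer number of steps")
  n_steps <- round(n_steps)
  if (n_steps %% 2L != 0L)
    stop("odd step count: a balanced sequence is impossible")
  template <- rep(c(1, -1), each = n_steps / 2L)
  channels <- withr::with_seed(seed, {
    vapply(seq_len(n_conditions), function(i) sample(template),
           numeric(n_steps))
  })
  colnames(channels) <- flicker_condition_names(n_conditions)
  new_stimulus_protocol("flicker_cs", channels, rate_hz,
                        trigger_times_s = 0,
                        meta = list(center_diam_um = center_diam_um,
                                    seed = seed))
}

flicker_condition_names <- function(n) {
  base <- c("uv_center", "green_center", "uv_surround", "green_surround")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("cond", seq_len(n - 4)))
}

#' Interleaved chromatic flash protocol
#'
#' Builds the flash stimulus set used for cone recordings: UV and green
#' flashes for center (default 150 um spot), surround (annulus) and
#' full-field (default 700 um) conditions, interleaved within each
#' repetition block. Each trial is `pre_s` baseline, `flash_s` light on,
#' `post_s` recovery.
#'
#' @param center_diam_um,fullfield_diam_um stimulus geometry (metadata)
#' @param n_repeats repetitions per condition (>= 1)
#' @param rate_hz stimulus update rate (Hz)
#' @param pre_s,flash_s,post_s trial phase durations (s)
#' @param conditions character vector of condition names to include
#' @return a [new_stimulus_protocol()] object with 0/1 channels and a
#'   trial table (condition, t_on, t_off, rep)
#' @export
make_flash_protocol <- function(center_diam_um = 150, fullfield_diam_um = 700,
                                n_repeats = 25, rate_hz = 100,
                                pre_s = 1, flash_s = 1, post_s = 1,
                                conditions = c("uv_center", "green_center",
                                               "uv_surround", "green_surround",
                                               "uv_fullfield", "green_fullfield")) {
  stopifnot(n_repeats >= 1, rate_hz > 0)
  trial_len_s <- pre_s + flash_s + post_s
  trial_len <- round(trial_len_s * rate_hz)
  n_cond <- length(conditions)
  n_trials <- n_cond * n_repeats
  channels <- matrix(0, nrow = trial_len * n_trials, ncol = n_cond,
                     dimnames = list(NULL, conditions))
  trial_table <- vector("list", n_trials)
  k <- 0L
  for (rep_i in seq_len(n_repeats)) {
    for (ci in seq_len(n_cond)) {
      k <- k + 1L
      t0 <- (k - 1L) * trial_len_s
      on <- round((t0 + pre_s) * rate_hz) + 1L
      off <- round((t0 + pre_s + flash_s) * rate_hz)
      channels[on:off, ci] <- 1
      trial_table[[k]] <- data.frame(condition = conditions[ci],
                                     t_on = t0, t_off = t0 + trial_len_s,
                                     rep = rep_i)
    }
  }
  trial_table <- do.call(rbind, trial_table)
  new_stimulus_protocol("flash_center_surround", channels, rate_hz,
                        trigger_times_s = trial_table$t_on,
                        trial_table = trial_table,
                        meta = list(center_diam_um = center_diam_um,
                                    fullfield_diam_um = fullfield_diam_um,
                                    pre_s = pre_s, flash_s = flash_s,
                                    post_s = post_s))
}

#' Sinusoidal center-surround modulation
#'
#' 2 Hz sine modulation of UV and green, center and surround, used for the
#' phase/F1 chromatic analysis.
#'
#' @param freq_hz modulation frequency (Hz)
#' @param duration_s duration per repetition (s)
#' @param n_repeats repetitions
#' @param rate_hz sample rate of the stimulus trace (Hz)
#' @export
make_sine_protocol <- function(freq_hz = 2, duration_s = 10, n_repeats = 3,
                               rate_hz = 100) {
  n <- round(duration_s * n_repeats * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  s <- sin(2 * pi * freq_hz * t)
  channels <- cbind(uv_center = s, green_center = s,
                    uv_surround = s, green_surround = s)
  new_stimulus_protocol("sine_cs", channels, rate_hz,
                        trigger_times_s = duration_s * (seq_len(n_repeats) - 1),
                        meta = list(freq_hz = freq_hz))
}

#' Full-field chirp template
#'
#' Piecewise-analytic waveform mimicking the standard functional-typing
#' chirp: an onset step, a frequency sweep and a contrast sweep. Only the
#' relative shape matters for template matching, not absolute calibration.
#'
#' @param duration_s total duration (s)
#' @param rate_hz sample rate (Hz)
#' @return numeric stimulus trace in [0, 1]
#' @export
make_chirp_template <- function(duration_s = 32, rate_hz = 100) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  s <- numeric(length(t))
  s[t >= 2 & t < 5] <- 1                                  # onset step
  seg <- t >= 8 & t < 18                                  # accelerating sweep
  u <- (t[seg] - 8) / 10
  s[seg] <- 0.5 + 0.5 * sin(2 * pi * (0.5 * u + 3.5 * u^2) * 10 / 10)
  seg <- t >= 21 & t < 29                                 # contrast sweep @2Hz
  u <- (t[seg] - 21) / 8
  s[seg] <- 0.5 + 0.5 * u * sin(2 * pi * 2 * (t[seg] - 21))
  s
}

#' Moving-bar response template axis
#'
#' Returns the eight motion directions (deg) of the moving-bar stimulus.
#' @export
bar_directions <- function() seq(0, 315, by = 45)
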