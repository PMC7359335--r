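#' Signed response area with polarity flag
#'
#' Response magnitude of a kernel relative to a reference center kernel,
#' signed by polarity: the baseline-subtracted kernel is projected onto the
#' baseline-subtracted reference over the response window (a matched
#' filter, in area units), so a kernel anticorrelated with the center
#' kernel gets a negative area — e.g. an antagonistic surround. Compared
#' with a rectified area, the projection mixes the channels linearly and
#' does not inflate weak channels with kernel sampling noise.
#'
#' @param x kernel or trace (numeric)
#' @param reference reference center kernel, same length as `x`
#' @param window integer indices of the response window (default: all)
#' @param baseline integer indices averaged for baseline subtraction
#'   (default: none)
#' @param dt sample spacing (for area units)
#' @return list(area, rho, polarity = "expected"/"antagonistic"/NA)
#' @export
signed_f_area <- function(x, reference, window = seq_along(x),
                          baseline = integer(0), dt = 1) {
  if (length(baseline)) {
    x <- x - mean(x[baseline])
    reference <- reference - mean(reference[baseline])
  }
  xs <- x[window]
  rs <- reference[window]
  if (length(xs) < 2 || anyNA(xs) || anyNA(rs) ||
      stats::sd(xs) == 0 || stats::sd(rs) == 0)
    return(list(area = 0, rho = NA_real_, polarity = NA_character_))
  rho <- stats::cor(xs, rs)
  area <- sum(xs * rs) / sqrt(sum(rs^2)) * dt * length(rs) / sqrt(length(rs))
  list(area = area,
       rho = rho,
       polarity = if (area < 0) "antagonistic" else "expected")
}

#' Net signed response area of a flash trace
#'
#' For flash (OPL) traces the polarity flag comes straight from the sign of
#' the response: the net baseline-subtracted area over the response window.
#' Negative = glutamate decrease (the expected center/full-field polarity
#' of cones), positive = increase (the expected antagonistic-surround
#' polarity).
#'
#' @param trace median response trace
#' @param window indices of the response window
#' @param baseline indices averaged for baseline subtraction
#' @param dt sample spacing
#' @return signed net area
#' @export
flash_f_area <- function(trace, window, baseline, dt = 1) {
  sum(trace[window] - mean(trace[baseline])) * dt
}

#' Spectral contrast
#'
#' Chromatic-preference statistic comparing green and UV response
#' magnitudes, with three cases selected by the polarity flags:
#'
#' * same polarity (both expected or both antagonistic): Michelson
#'   contrast `(|F_g| - |F_uv|) / (|F_g| + |F_uv|)`, in [-1, 1] (-1 pure
#'   UV, +1 pure green);
#' * green expected, UV antagonistic: `1 + |F_uv| / |F_g|` (> 1);
#' * UV expected, green antagonistic: `1 - |F_g| / |F_uv|` (< 1).
#'
#' @param f_green,f_uv response area magnitudes (absolute values are taken)
#' @param antagonistic_green,antagonistic_uv logical polarity flags
#' @return list(sc, case = "michelson"/"uv_antagonistic"/
#'   "green_antagonistic"); sc is NA with case "undefined" when both areas
#'   are zero or a required denominator is zero
#' @export
spectral_contrast <- function(f_green, f_uv, antagonistic_green = FALSE,
                              antagonistic_uv = FALSE) {
  g <- abs(f_green); u <- abs(f_uv)
  if (g == 0 && u == 0)
    return(list(sc = NA_real_, case = "undefined"))
  if (antagonistic_green == antagonistic_uv) {
    sc <- (g - u) / (g + u)
    if (antagonistic_green) sc <- -sc   # both antagonistic: roles swap
    return(list(sc = sc, case = "michelson"))
  }
  if (antagonistic_uv) {
    if (g == 0) return(list(sc = NA_real_, case = "undefined"))
    return(list(sc = 1 + u / g, case = "uv_antagonistic"))
  }
  if (u == 0) return(list(sc = NA_real_, case = "undefined"))
  list(sc = 1 - g / u, case = "green_antagonistic")
}

#' Spectral contrast from signed areas
#'
#' Convenience wrapper deriving the polarity flags from the signs of the
#' areas against the expected sign of the condition (+1 or -1), then
#' applying [spectral_contrast()]. A zero area counts as expected polarity.
#'
#' @param area_green,area_uv signed response areas
#' @param expected_sign expected deflection sign of the condition
#' @export
sc_from_signed_areas <- function(area_green, area_uv, expected_sign = -1) {
  ant_g <- area_green != 0 & sign(area_green) != expected_sign
  ant_u <- area_uv != 0 & sign(area_uv) != expected_sign
  spectral_contrast(area_green, area_uv, ant_g, ant_u)
}

#' Center-surround spectral-contrast difference
#'
#' SC_Diff = SC_surround - SC_center; large values mean chromatically
#' distinct center and surround.
#'
#' @param sc_surround,sc_center spectral contrasts (NA propagates)
#' @export
sc_diff <- function(sc_surround, sc_center) sc_surround - sc_center

#' Full-field color opponency
#'
#' Pearson correlation between the UV and green stimulus-triggered event
#' kernels at stimulus onset and offset (each phase requires both colors'
#' kernels with event quality above `qi_threshold`). Opponency =
#' min(rho_onset, rho_offset) over the defined phases; a cell is
#' color-opponent when either rho drops below `rho_criterion` (-0.3).
#'
#' @param event_kernels output of [fullfield_event_kernels()]
#' @param qi_threshold minimum [qi_event()] per kernel (default 0.25)
#' @param rho_criterion opponency criterion (default -0.3)
#' @return list(rho_onset, rho_offset, opponency, is_opponent); all NA when
#'   no phase is defined
#' @export
fullfield_opponency <- function(event_kernels, qi_threshold = 0.25,
                                rho_criterion = -0.3) {
  phase_rho <- function(phase) {
    ku <- event_kernels$uv[[phase]]
    kg <- event_kernels$green[[phase]]
    if (is.null(ku) || is.null(kg)) return(NA_real_)
    if (qi_event(ku) <= qi_threshold || qi_event(kg) <= qi_threshold)
      return(NA_real_)
    if (stats::sd(ku$kernel) == 0 || stats::sd(kg$kernel) == 0)
      return(NA_real_)
    stats::cor(ku$kernel, kg$kernel)
  }
  rho_on <- phase_rho("onset")
  rho_off <- phase_rho("offset")
  defined <- c(onset = rho_on, offset = rho_off)
  defined <- defined[!is.na(defined)]
  if (!length(defined))
    return(list(rho_onset = rho_on, rho_offset = rho_off,
                opponency = NA_real_, is_opponent = NA))
  list(rho_onset = rho_on, rho_offset = rho_off,
       opponency = min(defined),
       is_opponent = any(defined < rho_criterion))
}

#' Sine response phase and fundamental amplitude
#'
#' Cross-correlates the mean response with the sinusoidal stimulus and
#' converts the lag of maximal correlation into degrees (wrapped to
#' [0, 360)); the F1 amplitude is the discrete-Fourier amplitude at the
#' stimulus frequency.
#'
#' @param mean_trace mean response trace
#' @param sine_stimulus stimulus trace, same sampling
#' @param rate_hz sample rate
#' @param freq_hz stimulus frequency (default 2)
#' @return list(phase_deg, f1_amplitude)
#' @export
sine_phase_f1 <- function(mean_trace, sine_stimulus, rate_hz, freq_hz = 2) {
  period <- rate_hz / freq_hz
  if (length(mean_trace) < period) stop("trace shorter than one period")
  n <- min(length(mean_trace), length(sine_stimulus))
  x <- mean_trace[seq_len(n)] - mean(mean_trace[seq_len(n)])
  s <- sine_stimulus[seq_len(n)] - mean(sine_stimulus[seq_len(n)])
  lags <- 0:(ceiling(period) - 1)
  cc <- vapply(lags, function(l)
    sum(x[(l + 1):n] * s[1:(n - l)]), numeric(1))
  lag_best <- lags[which.max(cc)]
  phase_deg <- (lag_best / rate_hz * freq_hz * 360) %% 360
  t <- (seq_len(n) - 1) / rate_hz
  f1 <- 2 * Mod(mean(x * exp(-2i * pi * freq_hz * t)))
  list(phase_deg = phase_deg, f1_amplitude = f1)
}

#' Polar binning of response phases
#'
#' Bins phases at `bin_deg` resolution and normalizes the histogram by its
#' mean F1 amplitude, the summarizer used for chromatic sine analyses.
#'
#' @param phase_deg phases in degrees
#' @param f1 matching F1 amplitudes
#' @param bin_deg bin width (default 15)
#' @return data.frame(bin_start_deg, count, norm_count)
#' @export
bin_phases <- function(phase_deg, f1, bin_deg = 15) {
  edges <- seq(0, 360, by = bin_deg)
  bins <- cut(phase_deg %% 360, edges, right = FALSE, labels = FALSE)
  counts <- tabulate(bins, nbins = length(edges) - 1)
  data.frame(bin_start_deg = edges[-length(edges)], count = counts,
             norm_count = counts / mean(f1))
}
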