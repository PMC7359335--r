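#' Map a target spectral contrast to UV/green response weights
#'
#' Inverse of the three-case spectral-contrast statistic: given a target SC
#' and the expected response polarity of the condition (`expected_sign` = -1
#' for e.g. a cone center, where light decreases glutamate release; +1 for
#' an antagonistic surround), returns signed (green, UV) weights whose
#' direct-weight SC equals the target. Magnitudes are normalized to sum
#' to 1.
#'
#' SC in [-1, 1] yields same-polarity weights (Michelson case); SC > 1
#' yields an expected-polarity green weight with an antagonistic UV weight;
#' SC < -1 the reverse.
#'
#' @param sc numeric vector of target spectral contrasts
#' @param expected_sign +1 or -1, the expected trace deflection
#' @return data.frame with columns w_green, w_uv
#' @export
sc_to_weights <- function(sc, expected_sign = -1) {
  stopifnot(expected_sign %in% c(-1, 1))
  n <- length(sc)
  w_g <- numeric(n); w_uv <- numeric(n)
  mich <- abs(sc) <= 1
  w_g[mich] <- (1 + sc[mich]) / 2 * expected_sign
  w_uv[mich] <- (1 - sc[mich]) / 2 * expected_sign
  hi <- sc > 1                               # UV antagonistic
  r <- sc[hi] - 1
  w_g[hi] <- expected_sign / (1 + r)
  w_uv[hi] <- -expected_sign * r / (1 + r)
  lo <- sc < -1                              # green antagonistic
  r <- 1 - sc[lo]
  w_uv[lo] <- expected_sign / (1 + r)
  w_g[lo] <- -expected_sign * r / (1 + r)
  data.frame(w_green = w_g, w_uv = w_uv)
}

#' Spectral contrast implied by a pair of signed weights
#'
#' Forward map from signed (green, UV) weights to the three-case SC, used
#' to verify ground-truth populations. A weight whose sign matches
#' `expected_sign` is "expected", otherwise antagonistic.
#'
#' @inheritParams sc_to_weights
#' @param w_green,w_uv signed weights
#' @export
weights_to_sc <- function(w_green, w_uv, expected_sign = -1) {
  mapply(function(g, u) {
    if (g == 0 && u == 0) return(NA_real_)
    g_exp <- sign(g) == expected_sign || g == 0
    u_exp <- sign(u) == expected_sign || u == 0
    ag <- abs(g); au <- abs(u)
    if (g_exp && u_exp) (ag - au) / (ag + au)
    else if (g_exp && !u_exp) 1 + au / ag
    else if (!g_exp && u_exp) 1 - ag / au
    else -(ag - au) / (ag + au)   # both antagonistic: Michelson on flipped sign
  }, w_green, w_uv)
}

# Layer-specific defaults for the dorso-ventral chromatic gradient:
# population means/s.d. of center and surround SC at the ventral and dorsal
# poles. Cones (OPL) are Off units (expected center sign -1, antagonistic
# surround +1); IPL/GCL polarity is per-cell.
default_gradient_params <- function(layer) {
  switch(layer,
    OPL = list(center = list(ventral = c(mean = -0.7, sd = 0.43),
                             dorsal  = c(mean = 0.38, sd = 0.44)),
               surround = list(ventral = c(mean = 1.2, sd = 0.42),
                               dorsal  = c(mean = 0.39, sd = 1.02)),
               midpoint_mm = 0, slope_mm = 0.25),
    IPL = list(center = list(ventral = c(mean = -0.44, sd = 0.24),
                             dorsal  = c(mean = 0.1,  sd = 0.22)),
               surround = list(ventral = c(mean = 0.21, sd = 0.27),
                               dorsal  = c(mean = 0.03, sd = 0.19)),
               midpoint_mm = 0, slope_mm = 0.25),
    GCL = list(center = list(ventral = c(mean = -0.35, sd = 0.27),
                             dorsal  = c(mean = 0.06, sd = 0.25)),
               surround = list(ventral = c(mean = 0.21, sd = 0.82),
                               dorsal  = c(mean = 0.17, sd = 0.62)),
               midpoint_mm = 0, slope_mm = 0.25),
    stop("unknown layer: ", layer))
}

logistic_blend <- function(pos_mm, ventral, dorsal, midpoint, slope) {
  w <- 1 / (1 + exp(-(pos_mm - midpoint) / slope))   # 0 ventral -> 1 dorsal
  ventral + w * (dorsal - ventral)
}

#' Generate a ground-truth cell population
#'
#' Draws cells along the dorso-ventral axis with center and surround UV/green
#' weights following a logistic opsin-expression gradient: ventral cells are
#' UV-dominant in their center, and (for the default parameters) carry a
#' green-shifted antagonistic surround, emulating the rod/horizontal-cell
#' drive. Per-cell center and surround SC are drawn from position-dependent
#' normal distributions whose poles default to the reported population means
#' of each layer, then converted to signed weights with [sc_to_weights()].
#'
#' @param n_cells number of cells (>= 1)
#' @param layer "OPL", "IPL" or "GCL"
#' @param dorsoventral_range_mm length-2 range of signed distance from the
#'   optic nerve (negative = ventral)
#' @param gradient_params list as returned by `default_gradient_params`;
#'   override to pin population means
#' @param group_templates template library (see [make_group_templates()]);
#'   required for GCL populations
#' @param seed integer seed
#' @return data.frame of cells (one row each) with signed weights, polarity,
#'   kinetics, ground-truth SC columns (`sc_center_truth`, `sc_surround_truth`)
#'   and an `is_opponent_truth` flag
#' @export
make_population <- function(n_cells, layer = c("OPL", "IPL", "GCL"),
                            dorsoventral_range_mm = c(-2, 2),
                            gradient_params = NULL,
                            group_templates = NULL, seed = 1) {
  stopifnot(n_cells >= 1)
  layer <- match.arg(layer)
  gp <- gradient_params %||% default_gradient_params(layer)
  if (layer == "GCL" && is.null(group_templates))
    stop("GCL populations require a non-empty group_templates set")
  withr::with_seed(seed, {
    pos <- stats::runif(n_cells, dorsoventral_range_mm[1], dorsoventral_range_mm[2])
    mu_c <- logistic_blend(pos, gp$center$ventral["mean"], gp$center$dorsal["mean"],
                           gp$midpoint_mm, gp$slope_mm)
    sd_c <- logistic_blend(pos, gp$center$ventral["sd"], gp$center$dorsal["sd"],
                           gp$midpoint_mm, gp$slope_mm)
    mu_s <- logistic_blend(pos, gp$surround$ventral["mean"], gp$surround$dorsal["mean"],
                           gp$midpoint_mm, gp$slope_mm)
    sd_s <- logistic_blend(pos, gp$surround$ventral["sd"], gp$surround$dorsal["sd"],
                           gp$midpoint_mm, gp$slope_mm)
    sc_c <- stats::rnorm(n_cells, mu_c, sd_c)
    sc_s <- stats::rnorm(n_cells, mu_s, sd_s)
    polarity <- if (layer == "OPL") rep("Off", n_cells)
                else sample(c("On", "Off"), n_cells, replace = TRUE)
    e_center <- ifelse(polarity == "Off", -1, 1)
    e_surround <- -e_center            # expected surround is antagonistic
    wc <- sc_to_weights(sc_c, expected_sign = -1)
    ws <- sc_to_weights(sc_s, expected_sign = 1)
    # flip whole receptive field for On cells (sign convention per polarity)
    flip <- e_center / -1
    cells <- data.frame(
      cell_id = seq_len(n_cells),
      position_mm = pos,
      layer = layer,
      ipl_depth = if (layer == "IPL") stats::runif(n_cells, -0.1, 1.1) else NA_real_,
      polarity = polarity,
      w_center_green = wc$w_green * flip,
      w_center_uv = wc$w_uv * flip,
      w_surround_green = ws$w_green * flip,
      w_surround_uv = ws$w_uv * flip,
      amplitude = stats::runif(n_cells, 0.8, 1.2),
      kinetics_tau_s = stats::runif(n_cells, 0.08, 0.2),
      sc_center_truth = sc_c,
      sc_surround_truth = sc_s,
      group_id = if (layer == "GCL")
        sample(group_templates$group_id, n_cells, replace = TRUE) else NA_integer_,
      stringsAsFactors = FALSE)
    # full-field weights: center + surround per color; opponent if the two
    # colors pull in opposite directions with non-negligible magnitude
    ff_uv <- cells$w_center_uv + cells$w_surround_uv
    ff_g <- cells$w_center_green + cells$w_surround_green
    cells$is_opponent_truth <- sign(ff_uv) != sign(ff_g) &
      pmin(abs(ff_uv), abs(ff_g)) > 0.05
    cells
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise s.d. for a target signal-to-noise ratio
#'
#' Noise amplitude is expressed relative to the response amplitude: SNR =
#' (half peak-to-peak of the noiseless trace) / noise s.d.
#'
#' @param signal noiseless trace
#' @param snr target SNR (> 0)
#' @export
noise_sd_for_snr <- function(signal, snr) {
  stopifnot(snr > 0)
  amp <- (max(signal) - min(signal)) / 2
  amp / snr
}

#' Simulate a single-cell response trace
#'
#' Linear-nonlinear cascade: each stimulus channel is low-pass filtered with
#' an exponential-decay temporal filter (time constant `kinetics_tau_s`,
#' unit DC gain), weighted by the cell's signed condition weight, summed,
#' passed through a pointwise output nonlinearity, and sampled at the
#' acquisition rate with additive iid Gaussian noise. With the sign
#' conventions of [make_population()], a light increment in a driven
#' condition of an Off cell (e.g. a cone center) decreases the trace, the
#' release-decrease convention of outer-retina glutamate signals.
#'
#' @param cell one-row data.frame (a row of [make_population()])
#' @param protocol a [new_stimulus_protocol()] object
#' @param noise_sd additive Gaussian noise s.d. (trace units); see
#'   [noise_sd_for_snr()]
#' @param seed integer seed (noise reproducibility); NULL = no seeding
#' @param rate_hz output (acquisition) sample rate; defaults to the
#'   protocol rate
#' @param nonlinearity "softplus" (default) or "identity"
#' @param beta softplus sharpness; the default 0.5 is a mild rectifier
#'   whose gain varies by about 12% over the unit drive range, keeping the
#'   cascade's chromatic amplitude ratios recoverable by linear analyses
#' @return numeric trace with attributes `rate_hz` and `time_s`
#' @export
simulate_cell_response <- function(cell, protocol, noise_sd = 0, seed = NULL,
                                   rate_hz = NULL,
                                   nonlinearity = c("softplus", "identity"),
                                   beta = 0.5) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(noise_sd >= 0)
  rate_hz <- rate_hz %||% protocol$rate_hz
  weights <- c(uv_center = cell$w_center_uv, green_center = cell$w_center_green,
               uv_surround = cell$w_surround_uv, green_surround = cell$w_surround_green,
               uv_fullfield = cell$w_center_uv + cell$w_surround_uv,
               green_fullfield = cell$w_center_green + cell$w_surround_green)
  cond <- colnames(protocol$channels)
  unknown <- setdiff(cond, names(weights))
  if (length(unknown))
    stop("protocol channels without a matching cell weight: ",
         paste(unknown, collapse = ", "))
  # fine internal grid for the temporal filter, then sample at rate_hz
  fine_hz <- max(4 * protocol$rate_hz, 4 * rate_hz, 100)
  n_fine <- round(protocol$duration_s * fine_hz)
  t_fine <- (seq_len(n_fine) - 0.5) / fine_hz
  step_idx <- pmin(floor(t_fine * protocol$rate_hz) + 1L, nrow(protocol$channels))
  a <- exp(-1 / (fine_hz * cell$kinetics_tau_s))
  drive <- numeric(n_fine)
  for (ci in cond) {
    s <- protocol$channels[step_idx, ci]
    filt <- stats::filter((1 - a) * s, a, method = "recursive")
    drive <- drive + weights[[ci]] * as.numeric(filt)
  }
  drive <- drive * cell$amplitude
  g <- switch(nonlinearity,
              identity = drive,
              softplus = log1p(exp(pmin(beta * drive, 30))) / beta)
  n_out <- round(protocol$duration_s * rate_hz)
  t_out <- (seq_len(n_out) - 0.5) / rate_hz
  y <- stats::approx(t_fine, g, xout = t_out, rule = 2)$y
  if (noise_sd > 0) {
    noise_fun <- function() stats::rnorm(n_out, 0, noise_sd)
    y <- y + if (is.null(seed)) noise_fun() else withr::with_seed(seed, noise_fun())
  }
  structure(y, rate_hz = rate_hz, time_s = t_out)
}
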