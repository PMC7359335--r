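#' Area-ratio quality index
#'
#' Shared form of the kernel and event quality indices:
#' Qi = 1 - |F_Area(Baseline)| / |F_Area(signal)|. 1 means no baseline
#' activity relative to the response, 0 means equal areas; negative values
#' are possible. A zero signal area returns -Inf, which fails every
#' threshold.
#'
#' @param signal_area,baseline_area signed areas under the curve
#' @export
qi_ratio <- function(signal_area, baseline_area) {
  ifelse(abs(signal_area) > 0, 1 - abs(baseline_area) / abs(signal_area), -Inf)
}

#' Kernel quality index
#'
#' Applies [qi_ratio()] to an event-triggered stimulus kernel. Areas are
#' rectified areas per unit time: the baseline window is the earliest 25%
#' of the lag window (farthest from the event, where a causal kernel must
#' be flat), the response window the latest 25% (immediately before the
#' event). A structureless kernel has comparable rectified area in both
#' windows and scores near 0; a clean kernel concentrates area in the
#' response window and scores near 1.
#'
#' @param kernel_set `kernel_set` from [event_triggered_kernels()]
#' @param condition channel name (e.g. "uv_center")
#' @export
qi_kernel <- function(kernel_set, condition) {
  if (isTRUE(kernel_set$empty)) return(-Inf)
  k <- kernel_set$kernels[, condition]
  n <- length(k)
  nb <- min(max(2L, floor(n / 4)), max(1L, floor(n / 2)))
  qi_ratio(mean(abs(k[(n - nb + 1L):n])), mean(abs(k[seq_len(nb)])))
}

#' Event-kernel quality index
#'
#' [qi_ratio()] on a stimulus-triggered event kernel, with rectified area
#' per unit time in the pre-step baseline window vs. the post-step response
#' window.
#'
#' @param event_kernel one `[[color]][[phase]]` element of
#'   [fullfield_event_kernels()]
#' @export
qi_event <- function(event_kernel) {
  if (is.null(event_kernel)) return(-Inf)
  pre <- event_kernel$time_s <= 0
  qi_ratio(mean(abs(event_kernel$kernel[!pre])),
           mean(abs(event_kernel$kernel[pre])))
}

#' Trial signal-to-noise quality index
#'
#' Qi = Var_t[ mean_r C ] / mean_r[ Var_t C ] for a T x R repetition matrix
#' C (time samples by repetitions). 1 for identical repetitions; about 1/R
#' for pure noise. Variances are population variances (divide by N).
#'
#' @param C numeric T x R matrix, T >= 2, R >= 2
#' @export
qi_snr <- function(C) {
  stopifnot(is.matrix(C), nrow(C) >= 2, ncol(C) >= 2)
  pvar <- function(x) mean((x - mean(x))^2)
  denom <- mean(apply(C, 2, pvar))
  if (denom == 0) stop("degenerate constant repetitions: zero variance")
  pvar(rowMeans(C)) / denom
}

#' Default quality-control thresholds
#'
#' All layer-specific inclusion thresholds with their standard defaults:
#' OPL flash Qi > 0.25 with hyperpolarizing center/full-field, antagonistic
#' surround area > |center area| / 10 for surround analysis; IPL/GCL kernel
#' Qi > 0.6 (UV or green center); GCL grouping additionally chirp Qi > 0.4
#' or bar Qi > 0.6; scan fields with under 50% of cells passing are dropped.
#'
#' @export
default_qc_config <- function() {
  list(qi_flash = 0.25, qi_kernel = 0.6, qi_chirp = 0.4, qi_bars = 0.6,
       qi_event = 0.25, surround_area_fraction = 0.1,
       field_pass_fraction = 0.5, opponency_rho = -0.3)
}

#' Apply layer-specific inclusion filters
#'
#' Filters a record table by the layer's quality rules and drops whole scan
#' fields in which fewer than the configured fraction of cells pass. Every
#' exclusion is written to an audit log with the rule that fired.
#'
#' Expected columns by layer: OPL `qi_fullfield` and/or `qi_center_surround`,
#' `f_area_center`, `f_area_fullfield`, `f_area_surround`; IPL/GCL
#' `qi_kernel_uv`, `qi_kernel_green`; GCL grouping also `qi_chirp`,
#' `qi_bars`. All need `roi_id`; `field_id` enables the field rule.
#'
#' @param records data.frame of per-ROI records
#' @param layer "OPL", "IPL" or "GCL"
#' @param config threshold list, see [default_qc_config()]
#' @return list(records = passing rows, audit = data.frame(roi_id, rule,
#'   value, threshold, pass), fields_dropped)
#' @export
apply_layer_filters <- function(records, layer = c("OPL", "IPL", "GCL"),
                                config = default_qc_config()) {
  layer <- match.arg(layer)
  audit <- list()
  note <- function(roi, rule, value, thr, pass)
    data.frame(roi_id = roi, rule = rule, value = value, threshold = thr,
               pass = pass)
  n <- nrow(records)
  pass <- rep(TRUE, n)
  if (layer == "OPL") {
    qi <- pmax(records$qi_fullfield %||% rep(-Inf, n),
               records$qi_center_surround %||% rep(-Inf, n))
    ok_qi <- qi > config$qi_flash
    hyper <- (records$f_area_center %||% rep(NA_real_, n)) < 0 |
             (records$f_area_fullfield %||% rep(NA_real_, n)) < 0
    hyper[is.na(hyper)] <- FALSE
    pass <- ok_qi & hyper
    audit <- c(audit, list(note(records$roi_id, "opl_flash_qi", qi,
                                config$qi_flash, ok_qi),
                           note(records$roi_id, "opl_hyperpolarizing",
                                as.numeric(hyper), 1, hyper)))
  } else {
    qik <- pmax(records$qi_kernel_uv, records$qi_kernel_green)
    pass <- qik > config$qi_kernel
    audit <- c(audit, list(note(records$roi_id, "kernel_qi", qik,
                                config$qi_kernel, pass)))
    if (layer == "GCL" && !is.null(records$qi_chirp)) {
      grp_ok <- records$qi_chirp > config$qi_chirp |
                records$qi_bars > config$qi_bars
      records$group_eligible <- grp_ok & pass
      audit <- c(audit, list(note(records$roi_id, "gcl_group_qi",
                                  pmax(records$qi_chirp, records$qi_bars),
                                  config$qi_chirp, grp_ok)))
    }
  }
  fields_dropped <- character(0)
  if (!is.null(records$field_id)) {
    frac <- tapply(pass, records$field_id, mean)
    fields_dropped <- names(frac)[frac < config$field_pass_fraction]
    in_dropped <- records$field_id %in% fields_dropped
    audit <- c(audit, list(note(records$roi_id, "field_pass_fraction",
                                as.numeric(frac[as.character(records$field_id)]),
                                config$field_pass_fraction, !in_dropped)))
    pass <- pass & !in_dropped
  }
  list(records = records[pass, , drop = FALSE],
       audit = do.call(rbind, audit),
       fields_dropped = fields_dropped)
}

#' Surround-analysis eligibility
#'
#' A cell enters the surround analysis only if its surround response is
#' antagonistic (glutamate increase, positive signed area) and exceeds a
#' tenth of the center response magnitude.
#'
#' @param f_area_surround,f_area_center signed areas
#' @param fraction magnitude fraction (default 1/10)
#' @export
surround_eligible <- function(f_area_surround, f_area_center,
                              fraction = 0.1) {
  f_area_surround > abs(f_area_center) * fraction
}
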