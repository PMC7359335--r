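#' Default run configuration
#'
#' All tunable parameters of the pipeline with their standard defaults:
#' stimulus parameters per layer (10 Hz / 180 s flicker for IPL, 5 Hz /
#' 300 s for GCL, 25-repeat flashes for OPL), acquisition rates, QC
#' thresholds (see [default_qc_config()]) and the master seed. The master
#' seed fans out to per-stage child seeds by fixed offsets so stages are
#' independently reproducible.
#'
#' @param layer "OPL", "IPL" or "GCL"
#' @param n_cells population size
#' @param seed master seed
#' @export
default_config <- function(layer = "IPL", n_cells = 100, seed = 1) {
  stim <- switch(layer,
    OPL = list(kind = "flash", n_repeats = 25, rate_hz = 100),
    IPL = list(kind = "flicker", rate_hz = 10, duration_s = 180,
               lag_window_s = 2),
    GCL = list(kind = "flicker", rate_hz = 5, duration_s = 300,
               lag_window_s = 1))
  acq_rate <- switch(layer, OPL = 3.9, IPL = 11.16, GCL = 7.8125)
  list(layer = layer, n_cells = n_cells, seed = seed,
       dorsoventral_range_mm = c(-2, -0.5),
       snr = 5, acq_rate_hz = acq_rate, stimulus = stim,
       qc = default_qc_config(), n_groups = 8)
}

config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Read / write a run configuration
#'
#' YAML round-trip of the configuration list.
#' @param config configuration list
#' @param path file path
#' @export
write_config <- function(config, path) yaml::write_yaml(config, path)

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write / read a stimulus protocol as JSON
#' @param protocol a stimulus protocol
#' @param path file path
#' @export
write_protocol_json <- function(protocol, path) {
  obj <- protocol
  obj$channels <- as.data.frame(obj$channels)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_stimulus_protocol(obj$kind, as.matrix(obj$channels), obj$rate_hz,
                        obj$trigger_times_s, obj$trial_table, obj$meta)
}

reference_center_condition <- function(kernels) {
  e_uv <- mean(abs(kernels$kernels[, "uv_center"]))
  e_g <- mean(abs(kernels$kernels[, "green_center"]))
  if (e_uv >= e_g) "uv_center" else "green_center"
}

#' Chromatic record from stimulus kernels
#'
#' Computes the per-cell chromatic summary from a set of event-triggered
#' center-surround kernels: signed response areas relative to the dominant
#' center kernel ([signed_f_area()]), center and surround spectral
#' contrast, SC_Diff and the kernel quality indices. The response window
#' is the latest quarter of the lag window, the baseline the earliest
#' quarter.
#'
#' Polarity handling: kernel signs are only defined relative to the
#' reference center kernel. When the cell's response polarity (`"On"` /
#' `"Off"`, e.g. from its IPL depth or achromatic responses) is supplied,
#' the reference's own absolute polarity is read off its event-locked
#' transition (last minus second-to-last lag bin: positive for a cell
#' driven by light increments) and compared with the expected polarity, so
#' center-opponent cells whose *antagonistic* color dominates are still
#' resolved. Without a polarity the dominant center color is assumed to
#' have the expected polarity. The expected surround polarity is always
#' antagonistic to the center.
#'
#' @param kernels `kernel_set` of the four center-surround conditions
#' @param polarity optional "On"/"Off" response polarity anchor
#' @return one-row data.frame (sc_center, sc_surround, sc_diff, case ids,
#'   qi_kernel_uv, qi_kernel_green, areas)
#' @export
kernel_chromatic_record <- function(kernels, polarity = NULL) {
  na_row <- data.frame(sc_center = NA_real_, sc_surround = NA_real_,
                       sc_diff = NA_real_, case_center = "undefined",
                       case_surround = "undefined",
                       qi_kernel_uv = -Inf, qi_kernel_green = -Inf,
                       f_area_uv_center = NA_real_, f_area_green_center = NA_real_,
                       f_area_uv_surround = NA_real_,
                       f_area_green_surround = NA_real_)
  if (isTRUE(kernels$empty)) return(na_row)
  n <- nrow(kernels$kernels)
  nb <- min(max(2L, floor(n / 4)), floor(n / 2))
  window <- (n - nb + 1L):n
  baseline <- seq_len(nb)
  ref <- kernels$kernels[, reference_center_condition(kernels)]
  dt <- kernels$lag_s[2] - kernels$lag_s[1]
  expected_sign <- 1
  if (!is.null(polarity) && !is.na(polarity)) {
    p <- if (identical(polarity, "On")) 1 else -1
    ref_sign <- sign(ref[n] - ref[n - 1])
    if (ref_sign == 0) ref_sign <- 1
    expected_sign <- if (ref_sign == p) 1 else -1
  }
  area <- lapply(colnames(kernels$kernels), function(ci)
    signed_f_area(kernels$kernels[, ci], ref, window, baseline, dt))
  names(area) <- colnames(kernels$kernels)
  a <- vapply(area, `[[`, numeric(1), "area")
  scc <- sc_from_signed_areas(a["green_center"], a["uv_center"],
                              expected_sign = expected_sign)
  scs <- sc_from_signed_areas(a["green_surround"], a["uv_surround"],
                              expected_sign = -expected_sign)
  data.frame(sc_center = scc$sc, sc_surround = scs$sc,
             sc_diff = sc_diff(scs$sc, scc$sc),
             case_center = scc$case, case_surround = scs$case,
             qi_kernel_uv = qi_kernel(kernels, "uv_center"),
             qi_kernel_green = qi_kernel(kernels, "green_center"),
             f_area_uv_center = a["uv_center"],
             f_area_green_center = a["green_center"],
             f_area_uv_surround = a["uv_surround"],
             f_area_green_surround = a["green_surround"])
}

#' Recover chromatic records from simulated flicker responses
#'
#' Full trace-level pipeline for center-surround flicker recordings: per
#' cell, simulate the acquisition-rate response at the requested SNR,
#' resample to 500 Hz and detrend, detect release/calcium events, estimate
#' the four event-triggered stimulus kernels and summarize them with
#' [kernel_chromatic_record()].
#'
#' @param cells population data.frame ([make_population()])
#' @param protocol flicker protocol
#' @param snr per-cell signal-to-noise ratio
#' @param seed integer seed (fans out per cell)
#' @param acq_rate_hz acquisition frame rate (Hz)
#' @param lag_window_s kernel lag window (s)
#' @param nonlinearity generator output nonlinearity (see
#'   [simulate_cell_response()])
#' @return data.frame: one chromatic record per cell plus cell id, truth SC
#' @export
recover_flicker_sc <- function(cells, protocol, snr = 5, seed = 1,
                               acq_rate_hz = 11.16, lag_window_s = 2,
                               nonlinearity = "softplus") {
  cell_seeds <- withr::with_seed(seed, sample.int(2^30, nrow(cells)))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    trace0 <- simulate_cell_response(cell, protocol, noise_sd = 0,
                                     rate_hz = acq_rate_hz,
                                     nonlinearity = nonlinearity)
    nsd <- if (is.finite(snr)) noise_sd_for_snr(trace0, snr) else 0
    trace <- as.numeric(trace0) +
      if (nsd > 0) withr::with_seed(cell_seeds[i],
                                    stats::rnorm(length(trace0), 0, nsd))
      else 0
    prep <- preprocess_traces(matrix(trace, 1), rate_hz = acq_rate_hz)
    ev <- detect_events(prep$traces[1, ], prep$rate_hz)
    kern <- event_triggered_kernels(ev, protocol, lag_window_s)
    rec <- kernel_chromatic_record(kern, polarity = cell$polarity)
    rec$n_events <- kern$n_events
    rec
  })
  out <- do.call(rbind, res)
  out <- cbind(cell_id = cells$cell_id, out,
               sc_center_truth = cells$sc_center_truth,
               sc_surround_truth = cells$sc_surround_truth,
               position_mm = cells$position_mm)
  rownames(out) <- NULL
  out
}

#' Recover chromatic records from simulated flash responses
#'
#' Trace-level pipeline for the chromatic flash protocol (OPL recordings):
#' per cell, simulate at the acquisition rate with noise, resample/detrend,
#' form per-condition trial medians, take net signed response areas over
#' the flash window (baseline = pre-flash window), and compute spectral
#' contrast per condition group. Expected polarity is a decrease for
#' center/full-field (cones are Off) and an increase for the antagonistic
#' surround. Per-condition [qi_snr()] indices are included.
#'
#' The detrending cutoff sits well below the condition repetition cycle
#' (six 3-s trials = 18 s): a cutoff near the cycle frequency would leak
#' filter undershoot from strong responses into the weak conditions that
#' follow them and corrupt their small areas.
#'
#' @inheritParams recover_flicker_sc
#' @param protocol flash protocol ([make_flash_protocol()])
#' @param acq_rate_hz acquisition frame rate (default OPL 3.9 Hz)
#' @param highpass_hz flash-path detrending cutoff (default 0.02)
#' @return data.frame of per-cell records (sc_center, sc_surround,
#'   sc_fullfield, cases, qi per condition, signed areas)
#' @export
recover_flash_sc <- function(cells, protocol, snr = 5, seed = 1,
                             acq_rate_hz = 3.9, highpass_hz = 0.02) {
  m <- protocol$meta
  rate <- 500
  pre_n <- round(m$pre_s * rate)
  flash_n <- round(m$flash_s * rate)
  baseline_idx <- seq_len(pre_n)
  window_idx <- pre_n + seq_len(flash_n)
  conds <- colnames(protocol$channels)
  cell_seeds <- withr::with_seed(seed, sample.int(2^30, nrow(cells)))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    trace0 <- simulate_cell_response(cell, protocol, noise_sd = 0,
                                     rate_hz = acq_rate_hz)
    nsd <- if (is.finite(snr)) noise_sd_for_snr(trace0, snr) else 0
    trace <- as.numeric(trace0) +
      if (nsd > 0) withr::with_seed(cell_seeds[i],
                                    stats::rnorm(length(trace0), 0, nsd))
      else 0
    prep <- preprocess_traces(matrix(trace, 1), rate_hz = acq_rate_hz,
                              highpass_hz = highpass_hz)
    tr <- prep$traces[1, ]
    med <- lapply(conds, function(cc)
      trial_median(tr, prep$rate_hz, protocol$trial_table, cc))
    names(med) <- conds
    areas <- vapply(med, function(mm)
      flash_f_area(mm$median_trace, window_idx, baseline_idx,
                   dt = 1 / rate), numeric(1))
    qi <- vapply(med, function(mm) qi_snr(mm$C), numeric(1))
    scc <- sc_from_signed_areas(areas["green_center"], areas["uv_center"],
                                expected_sign = -1)
    scs <- sc_from_signed_areas(areas["green_surround"], areas["uv_surround"],
                                expected_sign = 1)
    scf <- if (all(c("green_fullfield", "uv_fullfield") %in% conds))
      sc_from_signed_areas(areas["green_fullfield"], areas["uv_fullfield"],
                           expected_sign = -1)
    else list(sc = NA_real_, case = "undefined")
    data.frame(sc_center = scc$sc, sc_surround = scs$sc,
               sc_fullfield = scf$sc,
               sc_diff = sc_diff(scs$sc, scc$sc),
               case_center = scc$case, case_surround = scs$case,
               f_area_center = areas[["uv_center"]] + areas[["green_center"]],
               f_area_fullfield = if ("uv_fullfield" %in% conds)
                 areas[["uv_fullfield"]] + areas[["green_fullfield"]]
               else NA_real_,
               f_area_surround = areas[["uv_surround"]] + areas[["green_surround"]],
               f_area_uv_center = areas[["uv_center"]],
               f_area_green_center = areas[["green_center"]],
               f_area_uv_surround = areas[["uv_surround"]],
               f_area_green_surround = areas[["green_surround"]],
               qi_center_surround = max(qi[c("uv_center", "green_center",
                                             "uv_surround", "green_surround")]),
               qi_fullfield = if ("uv_fullfield" %in% conds)
                 max(qi[c("uv_fullfield", "green_fullfield")]) else -Inf)
  })
  out <- do.call(rbind, res)
  out <- cbind(cell_id = cells$cell_id, out,
               sc_center_truth = cells$sc_center_truth,
               sc_surround_truth = cells$sc_surround_truth,
               position_mm = cells$position_mm)
  rownames(out) <- NULL
  out
}

#' Run the pipeline end-to-end from a configuration
#'
#' Generates the ground-truth population, simulates responses to the
#' layer's stimulus, recovers per-cell chromatic records, applies the
#' layer's quality filters and computes field-level summaries. Outputs are
#' reproducible bit-identically for a fixed config (the bundle carries a
#' config hash for provenance).
#'
#' @param config list from [default_config()]
#' @return list(records, qc_audit, field_summary, config, config_hash)
#' @export
run_pipeline <- function(config = default_config()) {
  layer <- config$layer
  templates <- if (layer == "GCL") make_group_templates(config$n_groups,
                                                        seed = config$seed + 11)
               else NULL
  cells <- make_population(config$n_cells, layer,
                           dorsoventral_range_mm = config$dorsoventral_range_mm,
                           group_templates = templates,
                           seed = config$seed + 1)
  if (config$stimulus$kind == "flash") {
    protocol <- make_flash_protocol(n_repeats = config$stimulus$n_repeats,
                                    rate_hz = config$stimulus$rate_hz)
    records <- recover_flash_sc(cells, protocol, snr = config$snr,
                                seed = config$seed + 2,
                                acq_rate_hz = config$acq_rate_hz)
  } else {
    protocol <- make_flicker_protocol(rate_hz = config$stimulus$rate_hz,
                                      duration_s = config$stimulus$duration_s,
                                      seed = config$seed + 3)
    records <- recover_flicker_sc(cells, protocol, snr = config$snr,
                                  seed = config$seed + 2,
                                  acq_rate_hz = config$acq_rate_hz,
                                  lag_window_s = config$stimulus$lag_window_s)
  }
  records$roi_id <- records$cell_id
  records$field_id <- 1L
  if (layer == "GCL") records$group_id <- cells$group_id
  qc <- apply_layer_filters(records, layer, config$qc)
  passed <- qc$records
  field_summary <- data.frame(
    field_id = 1L,
    n_rois = nrow(records),
    n_pass = nrow(passed),
    s_field = if (any(is.finite(passed$sc_center)))
      field_entropy(passed$sc_center) else NA_real_)
  list(records = passed, all_records = records, qc_audit = qc$audit,
       field_summary = field_summary, cells = cells,
       config = config, config_hash = config_hash(config))
}

#' Export chromatic records as a tidy CSV
#'
#' One row per ROI — the table a downstream mixed-model or GAM analysis
#' would consume.
#'
#' @param records data.frame of records
#' @param path output path
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}
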