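# Small builders shared across test files. Everything is generated in code;
# sizes are desk-scale so the whole suite stays fast.

# one-row cell data.frame with explicit weights
make_test_cell <- function(w_center_uv = 0, w_center_green = 0,
                           w_surround_uv = 0, w_surround_green = 0,
                           polarity = "Off", tau = 0.15, amplitude = 1,
                           layer = "OPL") {
  data.frame(cell_id = 1L, position_mm = -1, layer = layer,
             ipl_depth = NA_real_, polarity = polarity,
             w_center_green = w_center_green, w_center_uv = w_center_uv,
             w_surround_green = w_surround_green, w_surround_uv = w_surround_uv,
             amplitude = amplitude, kinetics_tau_s = tau,
             sc_center_truth = NA_real_, sc_surround_truth = NA_real_,
             group_id = NA_integer_, stringsAsFactors = FALSE)
}

# movie where every pixel carries the same signal plus optional noise
make_shared_signal_movie <- function(dims = c(8, 8), n_frames = 100,
                                     noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    sig <- sin(seq_len(n_frames) / 5)
    px <- array(rep(sig, each = prod(dims)), dim = c(dims, n_frames))
    if (noise_sd > 0)
      px <- px + array(rnorm(length(px), 0, noise_sd), dim = dim(px))
    structure(list(pixels = px + 100, rate_hz = 7.8, um_per_px = 1,
                   layer = "GCL", position_mm = -1, chat_band_rows = NULL,
                   truth_mask = matrix(1L, dims[1], dims[2]),
                   truth_table = data.frame(cell_id = 1L, x_um = dims[2] / 2,
                                            y_um = dims[1] / 2, radius_um = 5),
                   protocol = NULL),
              class = "scan_field_movie")
  })
}

make_noise_movie <- function(dims = c(10, 10), n_frames = 500, seed = 1) {
  withr::with_seed(seed, {
    px <- array(rnorm(prod(dims) * n_frames), dim = c(dims, n_frames))
    structure(list(pixels = px + 100, rate_hz = 7.8, um_per_px = 1,
                   layer = "GCL", position_mm = -1, chat_band_rows = NULL,
                   truth_mask = matrix(0L, dims[1], dims[2]),
                   truth_table = data.frame(), protocol = NULL),
              class = "scan_field_movie")
  })
}

# naive per-event loop implementation of the event-triggered average,
# the independent oracle for the vectorized kernel computation
naive_event_kernels <- function(events, protocol, lag_window_s) {
  n_lags <- round(lag_window_s * protocol$rate_hz) + 1L
  lag_s <- -rev(seq_len(n_lags) - 1L) / protocol$rate_hz
  usable <- which(events$times_s > lag_window_s &
                    events$times_s <= protocol$duration_s)
  out <- matrix(0, n_lags, ncol(protocol$channels),
                dimnames = list(NULL, colnames(protocol$channels)))
  for (i in usable) {
    for (li in seq_along(lag_s)) {
      t_sample <- events$times_s[i] + lag_s[li]
      j <- min(max(floor(t_sample * protocol$rate_hz) + 1L, 1L),
               nrow(protocol$channels))
      out[li, ] <- out[li, ] + events$weights[i] * protocol$channels[j, ]
    }
  }
  out / length(usable)
}
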