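#' Dart-throwing mosaic placement with an exclusion zone
#'
#' Places points uniformly in a rectangle, rejecting candidates closer than
#' `exclusion_um` to an accepted point — the classic hard-core process that
#' reproduces the depleted first bins of retinal density recovery profiles.
#'
#' @param n_points number of points to place
#' @param field_um c(width, height) in um
#' @param exclusion_um minimum pairwise distance (um)
#' @param seed integer seed
#' @param max_tries attempts before giving up
#' @return n x 2 matrix of (x, y) positions in um
#' @export
place_mosaic <- function(n_points, field_um, exclusion_um, seed = 1,
                         max_tries = 20000) {
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, n_points, 2)
    k <- 0L; tries <- 0L
    while (k < n_points && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, 0, field_um[1]), stats::runif(1, 0, field_um[2]))
      if (k == 0L ||
          min(sqrt((pts[seq_len(k), 1] - cand[1])^2 +
                   (pts[seq_len(k), 2] - cand[2])^2)) >= exclusion_um) {
        k <- k + 1L
        pts[k, ] <- cand
      }
    }
    if (k < n_points)
      stop(sprintf("could not place %d points with a %.1f um exclusion zone",
                   n_points, exclusion_um))
    colnames(pts) <- c("x_um", "y_um")
    pts
  })
}

#' Simulate a scan-field movie
#'
#' Renders a population of cells into a pixel x pixel x frame fluorescence
#' movie. Cell centers are placed as a hard-core mosaic (terminal-scale
#' exclusion zone), each cell's simulated trace is spread over neighboring
#' pixels by a Gaussian disc profile (the shared-signal correlation
#' structure that correlation-based ROI detection exploits), a constant
#' baseline fluorescence is added, and every pixel receives independent
#' Gaussian noise. Frame-rate and pixel-grid defaults follow the recording
#' configuration of each layer (OPL 128x128 @ 3.9 Hz, IPL 64x56 @ 11.16 Hz,
#' GCL 64x64 @ 7.8125 Hz), scaled down freely for desk-scale tests.
#'
#' @param cells population data.frame ([make_population()]); its first
#'   `n_cells` rows are rendered
#' @param protocol stimulus protocol driving the cell traces
#' @param dims c(rows, cols) pixel grid
#' @param rate_hz frame rate
#' @param um_per_px pixel size
#' @param snr per-pixel peak signal to noise s.d. ratio (Inf = noiseless)
#' @param terminal_diam_um range of terminal/soma diameters (um)
#' @param seed integer seed
#' @param layer layer label stored in metadata
#' @param chat_band_rows two row indices (IPL x-z scans)
#' @param baseline constant fluorescence offset
#' @return `scan_field_movie`: list with `pixels` (rows x cols x frames),
#'   `truth_mask` (label matrix), `truth_table` (cell id, centroid),
#'   acquisition metadata and the generating protocol
#' @export
simulate_scan_field <- function(cells, protocol, dims = c(64, 64),
                                rate_hz = 3.9, um_per_px = 1,
                                snr = 5, terminal_diam_um = c(3, 7),
                                seed = 1, layer = "OPL",
                                chat_band_rows = NULL, baseline = 100) {
  n_cells <- nrow(cells)
  field_um <- c(dims[2], dims[1]) * um_per_px
  centers <- place_mosaic(n_cells, field_um,
                          exclusion_um = mean(terminal_diam_um), seed = seed)
  n_frames <- round(protocol$duration_s * rate_hz)
  withr::with_seed(seed + 1L, {
    radii <- stats::runif(n_cells, terminal_diam_um[1] / 2, terminal_diam_um[2] / 2)
    cell_seeds <- sample.int(2^30, n_cells)
  })
  px_x <- ((seq_len(dims[2])) - 0.5) * um_per_px
  px_y <- ((seq_len(dims[1])) - 0.5) * um_per_px
  signal <- array(0, dim = c(dims[1], dims[2], n_frames))
  truth_mask <- matrix(0L, dims[1], dims[2])
  best_profile <- matrix(0, dims[1], dims[2])
  traces <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    tr <- simulate_cell_response(cells[i, ], protocol, noise_sd = 0,
                                 rate_hz = rate_hz)
    traces[i, ] <- as.numeric(tr)[seq_len(n_frames)]
    dx2 <- outer(px_y, rep(centers[i, 2], dims[2]), function(a, b) (a - b)^2)
    dy2 <- outer(rep(centers[i, 1], dims[1]), px_x, function(a, b) (b - a)^2)
    d2 <- dx2 + dy2
    prof <- exp(-d2 / (2 * (radii[i] / 2)^2))
    member <- d2 <= radii[i]^2 & prof > best_profile
    truth_mask[member] <- i
    best_profile[member] <- prof[member]
    prof[prof < 0.05] <- 0
    idx <- which(prof > 0)
    if (length(idx)) {
      centered <- traces[i, ] - stats::median(traces[i, ])
      for (j in idx) {
        r <- (j - 1) %% dims[1] + 1
        cc <- (j - 1) %/% dims[1] + 1
        signal[r, cc, ] <- signal[r, cc, ] + prof[j] * centered
      }
    }
  }
  # SNR is defined against the typical (median) cell's response amplitude,
  # so half the population sits above and half below the nominal SNR
  cell_amp <- apply(traces, 1, function(x) max(abs(x - stats::median(x))))
  sig_amp <- stats::median(cell_amp)
  noise_sd <- if (is.finite(snr) && sig_amp > 0) sig_amp / snr else 0
  pixels <- signal + baseline
  if (noise_sd > 0) {
    pixels <- pixels + withr::with_seed(seed + 2L,
      array(stats::rnorm(length(pixels), 0, noise_sd), dim = dim(pixels)))
  }
  structure(
    list(pixels = pixels, rate_hz = rate_hz, um_per_px = um_per_px,
         layer = layer, position_mm = stats::median(cells$position_mm),
         chat_band_rows = chat_band_rows,
         truth_mask = truth_mask,
         truth_table = data.frame(cell_id = cells$cell_id[seq_len(n_cells)],
                                  x_um = centers[, 1], y_um = centers[, 2],
                                  radius_um = radii),
         truth_traces = traces,
         protocol = protocol),
    class = "scan_field_movie")
}

#' @export
print.scan_field_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scan_field_movie> %s: %dx%d px, %d frames @ %g Hz, %d truth cells\n",
              x$layer, d[1], d[2], d[3], x$rate_hz, nrow(x$truth_table)))
  invisible(x)
}
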