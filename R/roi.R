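#' Local correlation image
#'
#' For every pixel, the mean Pearson correlation of its time course with its
#' 8-connected neighbors (border pixels use the neighbors that exist).
#' Functional units spread one signal over adjacent pixels, so this image is
#' high inside release units and near zero in noise — the basis of ROI
#' detection. Zero-variance pixels contribute a correlation of 0.
#'
#' @param movie a `scan_field_movie` (or plain rows x cols x frames array)
#' @return matrix of mean neighbor correlations in [-1, 1]
#' @export
correlation_image <- function(movie) {
  px <- if (inherits(movie, "scan_field_movie")) movie$pixels else movie
  stopifnot(length(dim(px)) == 3, dim(px)[3] >= 2)
  if (!all(is.finite(px))) stop("movie contains non-finite pixel values")
  d <- dim(px)
  n <- d[3]
  mu <- apply(px, c(1, 2), mean)
  ss <- apply(px, c(1, 2), function(v) sqrt(sum((v - mean(v))^2)))
  z <- array(0, dim = d)
  ok <- ss > 0
  for (k in seq_len(n)) z[, , k] <- ifelse(ok, (px[, , k] - mu) / ss, 0)
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(d[1], d[1] + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(d[2], d[2] + dc)
    c0 <- c1 - dc
    prod_sum <- matrix(0, length(r0), length(c0))
    for (k in seq_len(n))
      prod_sum <- prod_sum + z[r0, c0, k] * z[r1, c1, k]
    acc[r0, c0] <- acc[r0, c0] + prod_sum
    cnt[r0, c0] <- cnt[r0, c0] + 1
  }
  acc / cnt
}

#' Segment ROIs from a correlation image
#'
#' Thresholds the correlation image (fixed threshold, or Otsu's split of its
#' histogram clamped to [0.1, 0.9] in `"auto"` mode), labels connected
#' components, splits components larger than the layer's terminal size by
#' watershed on the correlation image, and discards components outside the
#' configured equivalent-diameter range. Layer size bounds follow cone
#' terminals (3-7 um) and bipolar-cell terminals (1-4 um).
#'
#' @param corr_image output of [correlation_image()]
#' @param movie the source movie (for pixel size metadata); may be NULL if
#'   `um_per_px` is given
#' @param threshold numeric in (-1, 1) or "auto"
#' @param diameter_range_um c(min, max) equivalent diameter in um
#' @param um_per_px pixel size override
#' @return `roi_mask`: list with `labels` (integer matrix, ids 1..n), and
#'   `roi_table` (id, centroid row/col, centroid um, area_um2, diam_um),
#'   plus the threshold used
#' @export
segment_rois <- function(corr_image, movie = NULL, threshold = "auto",
                         diameter_range_um = c(3, 7), um_per_px = NULL) {
  um_per_px <- um_per_px %||%
    (if (!is.null(movie)) movie$um_per_px else 1)
  if (identical(threshold, "auto")) {
    scaled <- (corr_image + 1) / 2
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * 2 - 1
    threshold <- min(max(thr, 0.1), 0.9)
  }
  stopifnot(is.numeric(threshold), threshold > -1, threshold < 1)
  binary <- corr_image > threshold
  labels <- EBImage::bwlabel(EBImage::Image(binary * 1))
  labels <- EBImage::imageData(labels)
  max_area_px <- pi * (diameter_range_um[2] / 2)^2 / um_per_px^2
  # split oversized components by watershed on the correlation landscape
  big <- which(tabulate(labels[labels > 0]) > max_area_px)
  if (length(big)) {
    relief <- corr_image
    relief[!(labels %in% big)] <- 0
    relief <- matrix(relief, nrow(corr_image))
    ws <- EBImage::watershed(EBImage::Image(pmax(relief, 0)), tolerance = 0.05)
    ws <- EBImage::imageData(ws)
    keep <- !(labels %in% big)
    new_labels <- matrix(0L, nrow(labels), ncol(labels))
    new_labels[keep & labels > 0] <- labels[keep & labels > 0]
    offset <- max(labels)
    new_labels[!keep & ws > 0] <- as.integer(ws[!keep & ws > 0]) + offset
    labels <- new_labels
  }
  roi_mask_from_labels(labels, um_per_px, diameter_range_um, threshold)
}

roi_mask_from_labels <- function(labels, um_per_px, diameter_range_um,
                                 threshold = NA_real_) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- nrow(labels)
  tab <- lapply(ids, function(id) {
    idx <- which(labels == id)
    r <- (idx - 1) %% rows + 1
    cc <- (idx - 1) %/% rows + 1
    area_um2 <- length(idx) * um_per_px^2
    data.frame(id = id, centroid_row = mean(r), centroid_col = mean(cc),
               x_um = (mean(cc) - 0.5) * um_per_px,
               y_um = (mean(r) - 0.5) * um_per_px,
               area_um2 = area_um2,
               diam_um = 2 * sqrt(area_um2 / pi))
  })
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(id = integer(), centroid_row = numeric(), centroid_col = numeric(),
               x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
               diam_um = numeric())
  keep <- tab$diam_um >= diameter_range_um[1] & tab$diam_um <= diameter_range_um[2]
  dropped <- tab$id[!keep]
  labels[labels %in% dropped] <- 0L
  tab <- tab[keep, , drop = FALSE]
  # relabel to contiguous positive integers
  relab <- labels
  for (i in seq_along(tab$id)) relab[labels == tab$id[i]] <- i
  tab$id <- seq_len(nrow(tab))
  if (nrow(tab) == 0) warning("no ROI survived segmentation")
  structure(list(labels = relab, roi_table = tab, threshold = threshold,
                 um_per_px = um_per_px),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d ROIs (threshold %.3f)\n", nrow(x$roi_table),
              x$threshold))
  invisible(x)
}

#' Normalized IPL depth
#'
#' Linear depth coordinate where 0 is the On ChAT band and 1 the Off ChAT
#' band; values outside [0, 1] are allowed at the IPL margins.
#'
#' @param roi_centroid_row ROI centroid row (pixels)
#' @param chat_band_rows c(row_On, row_Off), distinct
#' @export
ipl_depth <- function(roi_centroid_row, chat_band_rows) {
  if (length(chat_band_rows) != 2 || chat_band_rows[1] == chat_band_rows[2])
    stop("chat_band_rows must be two distinct row indices")
  (roi_centroid_row - chat_band_rows[1]) / (chat_band_rows[2] - chat_band_rows[1])
}
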