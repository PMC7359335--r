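#' Density recovery profile
#'
#' For each point, distances to every other point in the field are binned
#' (default 2 um bins) and each bin count is normalized by its annulus
#' area; the per-point histograms are averaged. Under complete spatial
#' randomness the profile is flat at the overall density; a hard-core
#' mosaic depletes the first bins.
#'
#' @param points_um n x 2 matrix of positions (um)
#' @param bin_um bin width (um, default 2)
#' @param max_radius_um profile extent (um)
#' @param reference optional logical or integer subset of points used as
#'   annulus centers (all points remain potential neighbors). Restricting
#'   the reference to points at least `max_radius_um` from the field edge
#'   removes the truncated-annulus edge deficit.
#' @return data.frame(r_lo, r_hi, r_mid, density) in points per um^2, plus
#'   an `n_reference` attribute
#' @export
density_recovery_profile <- function(points_um, bin_um = 2,
                                     max_radius_um = 20, reference = NULL) {
  points_um <- as.matrix(points_um)
  edges <- seq(0, max_radius_um, by = bin_um)
  n_bins <- length(edges) - 1
  areas <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  n <- nrow(points_um)
  ref <- if (is.null(reference)) seq_len(n) else which(rep(TRUE, n) & reference)
  if (is.numeric(reference)) ref <- as.integer(reference)
  if (n < 2 || !length(ref)) {
    warning("fewer than 2 points: zero profile")
    dens <- rep(0, n_bins)
    ref <- integer(0)
  } else {
    d <- as.matrix(stats::dist(points_um))
    per_point <- vapply(ref, function(i) {
      di <- d[i, -i]
      counts <- tabulate(findInterval(di, edges, rightmost.closed = TRUE,
                                      left.open = TRUE), nbins = n_bins)
      counts / areas
    }, numeric(n_bins))
    dens <- rowMeans(per_point)
  }
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    density = dens)
  attr(out, "n_reference") <- length(ref)
  out
}

#' Field entropy of spectral-contrast values
#'
#' Shannon entropy of the binned SC distribution within one scan field:
#' S_Field = -sum_i p_i log2 p_i with bin width 0.2 (edges anchored at 0)
#' and p_i the bin proportions. 0 when all ROIs share a bin; log2(k) for a
#' uniform spread over k bins. A heterogeneity measure of chromatic tuning.
#'
#' @param sc_values finite SC values of one scan field
#' @param bin_size bin width (default 0.2)
#' @export
field_entropy <- function(sc_values, bin_size = 0.2) {
  sc_values <- sc_values[is.finite(sc_values)]
  if (!length(sc_values)) stop("no finite SC values")
  bins <- floor(sc_values / bin_size)
  p <- tabulate(factor(bins)) / length(bins)
  s <- -sum(p[p > 0] * log2(p[p > 0]))
  if (s == 0) 0 else s   # avoid IEEE negative zero for single-bin fields
}

#' Direction selectivity with permutation test
#'
#' Extracts the direction tuning curve as the first right-singular vector
#' of the trial-averaged time x direction response matrix (no manual time
#' window needed), sign-oriented so its inner product with the mean
#' response is positive. The direction-selectivity index is the length of
#' the vector sum of the tuning weights in the 2-D plane, normalized by the
#' total tuning magnitude (in [0, 1]; the raw vector length is also
#' returned). Significance comes from shuffling direction labels across
#' single trials `n_perm` times; p is the fraction of surrogate vector
#' lengths at least as large as the observed one.
#'
#' @param trials 3-D array time x directions x repetitions
#' @param directions_deg motion directions (default 8 x 45 deg)
#' @param n_perm permutation count (default 1000)
#' @param seed integer seed
#' @return list(dsi, vector_length, preferred_deg, tuning, p)
#' @export
direction_selectivity <- function(trials, directions_deg = bar_directions(),
                                  n_perm = 1000, seed = 1) {
  stopifnot(length(dim(trials)) == 3, dim(trials)[2] == length(directions_deg))
  theta <- directions_deg * pi / 180
  d <- dim(trials)
  flat <- matrix(trials, d[1], d[2] * d[3])   # single trials as columns
  # direction-label indicator (direction varies fastest in the flattened
  # array); trial means are flat %*% G / R
  G <- matrix(0, d[2] * d[3], d[2])
  G[cbind(seq_len(d[2] * d[3]), rep(seq_len(d[2]), times = d[3]))] <- 1
  tuning_of <- function(mean_mat) {
    if (all(mean_mat == 0)) return(NULL)
    # first right-singular vector via eigen of the small D x D cross-product
    cp <- crossprod(mean_mat)
    v <- eigen(cp, symmetric = TRUE)$vectors[, 1]
    if (sum(v * colMeans(mean_mat)) < 0) v <- -v
    v
  }
  dsi_of <- function(v) {
    z <- sum(v * exp(1i * theta))
    c(length = Mod(z), dsi = Mod(z) / sum(abs(v)),
      pref = (Arg(z) * 180 / pi) %% 360)
  }
  v <- tuning_of(flat %*% G / d[3])
  if (is.null(v))
    return(list(dsi = NA_real_, vector_length = NA_real_,
                preferred_deg = NA_real_, tuning = NULL, p = NA_real_))
  obs <- dsi_of(v)
  null_len <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      vp <- tuning_of(flat[, sample.int(d[2] * d[3]), drop = FALSE] %*% G / d[3])
      if (is.null(vp)) return(0)
      dsi_of(vp)[["length"]]
    }, numeric(1))
  })
  p <- mean(null_len >= obs[["length"]])
  list(dsi = obs[["dsi"]], vector_length = obs[["length"]],
       preferred_deg = obs[["pref"]], tuning = v, p = p)
}

#' Synthetic functional-group template library
#'
#' Builds mean chirp and moving-bar response templates for a set of
#' functional groups, as smooth random mixtures of On/Off/transient
#' components; a synthetic stand-in with the same interface as a template
#' library derived from real group means. Groups 1-32 are treated as
#' retinal ganglion cell groups, higher ids as displaced amacrine cells.
#'
#' @param n_groups number of groups
#' @param n_time_chirp,n_time_bar template lengths (samples)
#' @param seed integer seed
#' @return list(group_id, chirp = matrix, bar = matrix, is_ds, is_alpha)
#' @export
make_group_templates <- function(n_groups = 8, n_time_chirp = 249,
                                 n_time_bar = 100, seed = 1) {
  withr::with_seed(seed, {
    smooth_noise <- function(n) {
      x <- stats::rnorm(n)
      stats::filter(x, rep(1 / 15, 15), circular = TRUE) |> as.numeric()
    }
    chirp <- vapply(seq_len(n_groups), function(i) {
      y <- smooth_noise(n_time_chirp)
      (y - mean(y)) / stats::sd(y)
    }, numeric(n_time_chirp))
    bar <- vapply(seq_len(n_groups), function(i) {
      y <- smooth_noise(n_time_bar)
      (y - mean(y)) / stats::sd(y)
    }, numeric(n_time_bar))
    list(group_id = seq_len(n_groups), chirp = t(chirp), bar = t(bar),
         is_ds = seq_len(n_groups) %% 4 == 0,
         is_alpha = seq_len(n_groups) %% 5 == 0)
  })
}

#' Assign a cell to a functional group by match index
#'
#' Correlates a cell's chirp and moving-bar responses with candidate group
#' templates and combines the two correlations into a quality-weighted
#' match index Mi = Qi_Chirp/(Qi_Chirp+Qi_Bar) * r_Chirp +
#' Qi_Bar/(Qi_Chirp+Qi_Bar) * r_Bar. Before correlation the chirp trace is
#' shifted by 40 ms and boxcar-smoothed over 5 samples (chirp only), the
#' standard correction for a small frame-rate mismatch against the template
#' library. Candidates are restricted by class flags: direction-selective
#' cells match DS groups, alpha cells (soma area > 170 um^2) alpha groups,
#' all others the rest. The cell is assigned to the argmax group when its
#' Mi exceeds 0.5.
#'
#' @param chirp_trace,bar_trace mean response traces, sampled like the
#'   templates
#' @param qi_chirp,qi_bar response quality indices (positive)
#' @param templates template library ([make_group_templates()])
#' @param is_ds,soma_area_um2 restriction flags
#' @param rate_hz sample rate of the traces (for the 40 ms shift)
#' @param shift_s,boxcar time shift and chirp smoothing width
#' @return list(mi = named vector, assigned (group id or NA), r_chirp,
#'   r_bar, reason)
#' @export
assign_cluster <- function(chirp_trace, bar_trace, qi_chirp, qi_bar,
                           templates, is_ds = FALSE, soma_area_um2 = 100,
                           rate_hz = 7.8125, shift_s = 0.04, boxcar = 5) {
  is_alpha <- soma_area_um2 > 170
  cand <- if (is_ds) templates$is_ds
          else if (is_alpha) templates$is_alpha
          else !templates$is_ds & !templates$is_alpha
  if (!any(cand))
    return(list(mi = numeric(0), assigned = NA_integer_,
                r_chirp = numeric(0), r_bar = numeric(0),
                reason = "no candidate templates after class restriction"))
  shift_n <- round(shift_s * rate_hz)
  ch <- chirp_trace
  if (shift_n > 0 && shift_n < length(ch))
    ch <- c(ch[(shift_n + 1):length(ch)], rep(ch[length(ch)], shift_n))
  if (boxcar > 1)
    ch <- as.numeric(stats::filter(ch, rep(1 / boxcar, boxcar), sides = 2))
  ids <- templates$group_id[cand]
  r_chirp <- vapply(which(cand), function(g) {
    n <- min(length(ch), ncol(templates$chirp))
    stats::cor(ch[seq_len(n)], templates$chirp[g, seq_len(n)],
               use = "complete.obs")
  }, numeric(1))
  r_bar <- vapply(which(cand), function(g) {
    n <- min(length(bar_trace), ncol(templates$bar))
    stats::cor(bar_trace[seq_len(n)], templates$bar[g, seq_len(n)])
  }, numeric(1))
  wq <- qi_chirp / (qi_chirp + qi_bar)
  mi <- wq * r_chirp + (1 - wq) * r_bar
  names(mi) <- ids
  best <- which.max(mi)
  list(mi = mi,
       assigned = if (mi[best] > 0.5) ids[best] else NA_integer_,
       r_chirp = r_chirp, r_bar = r_bar,
       reason = if (mi[best] > 0.5) "assigned" else "max Mi below 0.5")
}

#' Group-level opponency permutation test
#'
#' Tests whether each functional group contains more (or fewer)
#' color-opponent cells than expected from its chromatic preference alone.
#' SC_Diff values are binned across all cells (bin 0.25, edges anchored at
#' 0). In each of `n_iter` iterations, every cell of the group is replaced
#' by a random *different* cell from the same SC_Diff bin with a center SC
#' within +/- `sc_center_tol`, and the percentage of opponent cells in the
#' surrogate set is recorded. The raw percentile of the observed percentage
#' within this null is reported, plus a two-sided p =
#' 2 * min(percentile, 1 - percentile) since both enrichment and depletion
#' are of interest. Groups at or below `min_n` cells are skipped. Cells
#' with no eligible partner are excluded from the surrogate draw (and
#' counted in `n_unmatched`).
#'
#' @param records data.frame with columns group_id, sc_center, sc_diff,
#'   is_opponent
#' @param n_iter iterations per group (default 10000)
#' @param seed integer seed
#' @param min_n minimum group size tested (default 15, exclusive)
#' @param sc_diff_bin SC_Diff stratification bin (default 0.25)
#' @param sc_center_tol center-SC matching tolerance (default 0.1)
#' @return data.frame per tested group: n_cells, observed_pct, null_mean,
#'   percentile, p_two_sided, direction, n_unmatched
#' @export
group_opponency_test <- function(records, n_iter = 10000, seed = 1,
                                 min_n = 15, sc_diff_bin = 0.25,
                                 sc_center_tol = 0.1) {
  stopifnot(all(c("group_id", "sc_center", "sc_diff", "is_opponent")
                %in% names(records)))
  records <- records[is.finite(records$sc_diff) & is.finite(records$sc_center) &
                       !is.na(records$is_opponent), , drop = FALSE]
  bin <- floor(records$sc_diff / sc_diff_bin)
  opp <- as.logical(records$is_opponent)
  groups <- sort(unique(records$group_id))
  res <- lapply(groups, function(g) {
    in_g <- which(records$group_id == g)
    n_g <- length(in_g)
    if (n_g <= min_n)
      return(data.frame(group_id = g, n_cells = n_g, observed_pct = NA_real_,
                        null_mean = NA_real_, percentile = NA_real_,
                        p_two_sided = NA_real_, direction = "skipped",
                        n_unmatched = NA_integer_))
    pools <- lapply(in_g, function(i) {
      cand <- which(bin == bin[i] &
                      abs(records$sc_center - records$sc_center[i]) <= sc_center_tol)
      setdiff(cand, i)
    })
    matched <- lengths(pools) > 0
    pools <- pools[matched]
    observed <- 100 * mean(opp[in_g[matched]])
    null_pct <- withr::with_seed(seed + g, {
      draws <- vapply(pools, function(p)
        opp[p[sample.int(length(p), n_iter, replace = TRUE)]],
        logical(n_iter))
      100 * rowMeans(draws)
    })
    pct_rank <- mean(null_pct < observed) + 0.5 * mean(null_pct == observed)
    data.frame(group_id = g, n_cells = n_g, observed_pct = observed,
               null_mean = mean(null_pct), percentile = pct_rank,
               p_two_sided = min(1, 2 * min(pct_rank, 1 - pct_rank)),
               direction = if (observed > mean(null_pct)) "enriched" else "depleted",
               n_unmatched = sum(!matched))
  })
  do.call(rbind, res)
}
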