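test_that("flicker sequences are balanced, independent and reproducible", {
  p <- make_flicker_protocol(4, rate_hz = 10, duration_s = 180, seed = 1)
  expect_equal(nrow(p$channels), 1800)
  expect_true(all(colSums(p$channels == 1) == 900))
  expect_equal(unname(colMeans(p$channels)), rep(0, 4))
  # GCL variant
  p5 <- make_flicker_protocol(4, rate_hz = 5, duration_s = 300, seed = 1)
  expect_equal(nrow(p5$channels), 1500)
  # minimal balanced sequence
  p2 <- make_flicker_protocol(4, rate_hz = 10, duration_s = 0.2, seed = 1)
  expect_equal(nrow(p2$channels), 2)
  expect_true(all(colSums(p2$channels) == 0))
  # pairwise near-uncorrelated (independent draws, n = 1800)
  cc <- cor(p$channels)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.08)
  # determinism
  expect_identical(make_flicker_protocol(4, 10, 180, seed = 1)$channels,
                   p$channels)
  expect_false(identical(make_flicker_protocol(4, 10, 180, seed = 2)$channels,
                         p$channels))
  expect_error(make_flicker_protocol(4, rate_hz = 10, duration_s = 0.15),
               "balanced|integer")
})

test_that("flash protocol interleaves conditions with correct trial table", {
  p <- make_flash_protocol(150, 700, n_repeats = 25)
  expect_equal(sum(p$trial_table$condition == "uv_center"), 25)
  expect_equal(length(unique(p$trial_table$condition)), 6)
  expect_equal(p$meta$center_diam_um, 150)
  expect_true(all(diff(p$trigger_times_s) > 0))
  p1 <- make_flash_protocol(100, 700, n_repeats = 1)
  expect_equal(nrow(p1$trial_table), 6)
  expect_equal(p1$meta$center_diam_um, 100)
  # channels are on only during flash epochs
  on_frac <- colMeans(p$channels)
  expect_equal(unname(on_frac), rep(1 / 18, 6), tolerance = 1e-6)
})

test_that("cell response follows the linear-nonlinear cascade", {
  flash <- make_flash_protocol(n_repeats = 2, rate_hz = 50)
  # all-zero weights, no noise: constant trace
  z <- simulate_cell_response(make_test_cell(), flash, noise_sd = 0)
  expect_equal(diff(range(z)), 0)
  # single driven pathway, Off polarity: decrease during UV center flash
  cell <- make_test_cell(w_center_uv = -1)
  tr <- simulate_cell_response(cell, flash, noise_sd = 0, rate_hz = 50)
  t_s <- attr(tr, "time_s")
  row <- subset(flash$trial_table, condition == "uv_center")[1, ]
  in_flash <- t_s > row$t_on + 1.2 & t_s < row$t_on + 2
  other <- subset(flash$trial_table, condition == "green_center")[1, ]
  in_other <- t_s > other$t_on + 1.2 & t_s < other$t_on + 2
  expect_lt(mean(tr[in_flash]), tr[1] - 0.1)
  expect_equal(mean(tr[in_other]), tr[1], tolerance = 1e-2)
  # linearity at identity nonlinearity: doubling weights doubles the trace
  c1 <- make_test_cell(w_center_uv = -0.4, w_surround_green = 0.3)
  c2 <- make_test_cell(w_center_uv = -0.8, w_surround_green = 0.6)
  t1 <- simulate_cell_response(c1, flash, 0, nonlinearity = "identity")
  t2 <- simulate_cell_response(c2, flash, 0, nonlinearity = "identity")
  expect_equal(2 * as.numeric(t1), as.numeric(t2), tolerance = 1e-10)
  # ventral cone template: UV center decrease, green surround increase
  vc <- make_test_cell(w_center_uv = -1, w_surround_green = 1)
  tv <- simulate_cell_response(vc, flash, 0, rate_hz = 50)
  surround <- subset(flash$trial_table, condition == "green_surround")[1, ]
  in_surr <- t_s > surround$t_on + 1.2 & t_s < surround$t_on + 2
  expect_lt(mean(tv[in_flash]), tv[1])
  expect_gt(mean(tv[in_surr]), tv[1])
  # deterministic under seed
  n1 <- simulate_cell_response(cell, flash, noise_sd = 0.1, seed = 5)
  n2 <- simulate_cell_response(cell, flash, noise_sd = 0.1, seed = 5)
  expect_identical(as.numeric(n1), as.numeric(n2))
  bad <- make_sine_protocol()
  colnames(bad$channels)[1] <- "bogus"
  expect_error(simulate_cell_response(cell, bad, 0), "matching cell weight")
})

test_that("population generator follows the dorso-ventral opsin gradient", {
  # ventral-only population: mean ground-truth center SC below zero
  pv <- make_population(200, "OPL", dorsoventral_range_mm = c(-2, -0.5),
                        seed = 3)
  expect_lt(mean(pv$sc_center_truth), 0)
  expect_true(all(is.finite(as.matrix(pv[, c("w_center_green", "w_center_uv",
                                             "w_surround_green",
                                             "w_surround_uv")]))))
  expect_true(all(pv$kinetics_tau_s > 0))
  # ventral cells UV-dominant in the center (default gradient); note that
  # strongly opponent draws (SC < -1) carry a larger antagonistic green
  # weight by construction, so dominance is asserted on the truth SC
  expect_gt(mean(pv$sc_center_truth < 0), 0.85)
  # across the full axis, position and truth SC correlate; the biological
  # scatter (the reported per-region s.d.) bounds the attainable rank
  # correlation well below 1
  pa <- make_population(1000, "OPL", dorsoventral_range_mm = c(-2, 2),
                        seed = 4)
  expect_gt(cor(pa$position_mm, pa$sc_center_truth, method = "spearman"), 0.6)
  # zero-slope gradient: all cells share the expected SC
  gp <- list(
    center = list(ventral = c(mean = 0.2, sd = 0), dorsal = c(mean = 0.2, sd = 0)),
    surround = list(ventral = c(mean = 0.1, sd = 0), dorsal = c(mean = 0.1, sd = 0)),
    midpoint_mm = 0, slope_mm = 0.25)
  pf <- make_population(50, "IPL", gradient_params = gp, seed = 5)
  expect_equal(var(pf$sc_center_truth), 0)
  expect_error(make_population(10, "GCL"), "group_templates")
})

test_that("weight mapping and spectral contrast are mutual inverses", {
  sc <- c(-1.6, -1, -0.44, 0, 0.38, 1, 1.2, 2.3)
  for (es in c(-1, 1)) {
    w <- sc_to_weights(sc, expected_sign = es)
    expect_equal(weights_to_sc(w$w_green, w$w_uv, expected_sign = es), sc)
    expect_equal(abs(w$w_green) + abs(w$w_uv), rep(1, length(sc)))
  }
})

test_that("scan fields have mosaic geometry and shared-signal ROIs", {
  prot <- make_flash_protocol(n_repeats = 2, rate_hz = 50)
  cells <- make_population(1, "OPL", seed = 2)
  mv <- simulate_scan_field(cells, prot, dims = c(16, 16), rate_hz = 3.9,
                            snr = Inf, seed = 1)
  # one cell, zero noise: truth mask one component, member pixels perfectly
  # correlated
  expect_equal(sort(unique(as.vector(mv$truth_mask))), c(0L, 1L))
  # member pixels carry one shared signal: pairwise correlations are 1
  member <- which(mv$truth_mask == 1)
  flat <- matrix(mv$pixels, 16 * 16, dim(mv$pixels)[3])
  cc <- cor(t(flat[member, ]))
  expect_gt(min(cc), 0.999)
  # mosaic respects the exclusion radius
  pts <- place_mosaic(40, c(93, 110), exclusion_um = 5, seed = 7)
  expect_gte(min(dist(pts)), 5)
  # DRP of mosaic centers has a depleted first bin (oracle: pairwise
  # distance histogram)
  drp <- density_recovery_profile(pts, bin_um = 2, max_radius_um = 20)
  expect_equal(sum(drp$density[drp$r_hi <= 4]), 0)
  expect_gt(mean(drp$density[drp$r_lo >= 10]), 0)
  # noise-dominated field: correlation image near zero
  nm <- make_noise_movie(c(10, 10), 400, seed = 3)
  expect_lt(abs(mean(correlation_image(nm))), 0.05)
})
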