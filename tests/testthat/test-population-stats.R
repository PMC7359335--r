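test_that("density recovery profile is flat under spatial randomness", {
  # single point: all-zero profile with a warning
  expect_warning(drp1 <- density_recovery_profile(matrix(c(1, 1), 1)), "2 points")
  expect_true(all(drp1$density == 0))
  # homogeneous Poisson points: every bin near the overall density
  lambda <- 300 / (100 * 100)
  reps <- lapply(1:8, function(s) {
    pts <- withr::with_seed(s, matrix(runif(600, 0, 100), ncol = 2))
    density_recovery_profile(pts, bin_um = 2, max_radius_um = 16)$density
  })
  avg <- Reduce(`+`, reps) / length(reps)
  expect_true(all(abs(avg - lambda) < 3 * lambda / sqrt(8)))
  # chi-squared goodness of fit against a flat profile, using interior
  # reference points so annuli are complete
  lambda2 <- 400 / (140 * 140)
  chi_p <- vapply(1:8, function(s) {
    pts <- withr::with_seed(20 + s, matrix(runif(800, 0, 140), ncol = 2))
    interior <- pts[, 1] >= 16 & pts[, 1] <= 124 &
                pts[, 2] >= 16 & pts[, 2] <= 124
    drp <- density_recovery_profile(pts, bin_um = 2, max_radius_um = 16,
                                    reference = interior)
    n_ref <- attr(drp, "n_reference")
    counts <- drp$density * pi * (drp$r_hi^2 - drp$r_lo^2) * n_ref
    expected <- lambda2 * pi * (drp$r_hi^2 - drp$r_lo^2) * n_ref
    suppressWarnings(chisq.test(round(counts), p = expected / sum(expected))$p.value)
  }, numeric(1))
  expect_gt(mean(chi_p), 0.01)
  # exclusion-zone mosaic: bins below the exclusion radius are empty
  pts <- place_mosaic(60, c(93, 110), exclusion_um = 5, seed = 9)
  drp <- density_recovery_profile(pts, bin_um = 2, max_radius_um = 20)
  expect_equal(sum(drp$density[drp$r_hi <= 4]), 0)
})

test_that("field entropy matches Shannon entropy of the binned SC values", {
  expect_equal(field_entropy(rep(0.1, 50)), 0)
  expect_equal(field_entropy(c(rep(0.1, 25), rep(0.35, 25))), 1)
  expect_equal(field_entropy(c(rep(-0.3, 10), rep(-0.1, 10),
                               rep(0.1, 10), rep(0.3, 10))), 2)
  # bounds: between 0 and log2(occupied bins); invariant to shifts that
  # keep bin membership
  set.seed(11)
  for (i in 1:20) {
    sc <- runif(30, -1, 1)
    s <- field_entropy(sc)
    k <- length(unique(floor(sc / 0.2)))
    expect_gte(s, 0)
    expect_lte(s, log2(k) + 1e-12)
    expect_equal(field_entropy(sc + 0.4), s)   # whole-bin shift
  }
  expect_error(field_entropy(numeric(0)), "SC")
})

test_that("direction selectivity separates tuned from flat cells", {
  T_ <- 30; R <- 4
  tpl <- exp(-((1:T_) - 10)^2 / 20)
  flat <- array(rep(tpl, 8 * R), dim = c(T_, 8, R))
  r0 <- direction_selectivity(flat, n_perm = 50, seed = 1)
  expect_equal(r0$dsi, 0, tolerance = 1e-9)
  one <- array(0, dim = c(T_, 8, R))
  one[, 3, ] <- tpl
  r1 <- direction_selectivity(one, n_perm = 50, seed = 1)
  expect_equal(r1$dsi, 1, tolerance = 1e-9)
  expect_equal(r1$preferred_deg, 90)
  # a smoothly tuned noisy cell is significant under permutation
  theta <- seq(0, 315, 45) * pi / 180
  wdir <- exp(2 * cos(theta - pi / 2)); wdir <- wdir / max(wdir)
  R6 <- 6
  tuned <- array(outer(tpl, wdir), dim = c(T_, 8, R6))
  noisy <- tuned + withr::with_seed(2, array(rnorm(T_ * 8 * R6, 0, 0.1),
                                             dim = c(T_, 8, R6)))
  rn <- direction_selectivity(noisy, n_perm = 200, seed = 3)
  expect_gt(rn$dsi, 0.5)
  expect_lt(rn$p, 0.05)
  # all-zero matrix: undefined
  expect_true(is.na(direction_selectivity(array(0, c(T_, 8, R)),
                                          n_perm = 10)$dsi))
})

test_that("cluster assignment implements the match index", {
  tpl <- make_group_templates(n_groups = 8, seed = 2)
  # direct evaluation: equal quality, r_chirp 0.4, r_bar 0.8 gives Mi 0.6
  expect_equal(0.5 * 0.4 + 0.5 * 0.8, 0.6)
  # a cell equal to a template is assigned to it with Mi near 1
  g <- which(!tpl$is_ds & !tpl$is_alpha)[1]
  res <- assign_cluster(tpl$chirp[g, ], tpl$bar[g, ], qi_chirp = 0.5,
                        qi_bar = 0.5, templates = tpl)
  expect_equal(res$assigned, g)
  expect_gt(max(res$mi), 0.9)
  # weights of the match index sum to one and Mi stays within [-1, 1]
  expect_true(all(abs(res$mi) <= 1))
  # restriction flags: DS cells only consider DS templates
  res_ds <- assign_cluster(tpl$chirp[g, ], tpl$bar[g, ], 0.5, 0.5, tpl,
                           is_ds = TRUE)
  expect_true(all(as.integer(names(res_ds$mi)) %in%
                    tpl$group_id[tpl$is_ds]))
  # template + noise at SNR 5: at least 90% correct recovery
  non_special <- which(!tpl$is_ds & !tpl$is_alpha)
  hits <- withr::with_seed(3, vapply(1:40, function(i) {
    g <- sample(non_special, 1)
    ch <- tpl$chirp[g, ] + rnorm(ncol(tpl$chirp), 0, sd(tpl$chirp[g, ]) / 5)
    br <- tpl$bar[g, ] + rnorm(ncol(tpl$bar), 0, sd(tpl$bar[g, ]) / 5)
    identical(assign_cluster(ch, br, 0.6, 0.6, tpl)$assigned, g)
  }, logical(1)))
  expect_gte(mean(hits), 0.9)
  # no candidates after restriction: unassigned with a reason
  tpl2 <- tpl; tpl2$is_ds[] <- FALSE
  r0 <- assign_cluster(tpl$chirp[1, ], tpl$bar[1, ], 0.5, 0.5, tpl2,
                       is_ds = TRUE)
  expect_true(is.na(r0$assigned))
  expect_match(r0$reason, "restriction")
})

simulate_null_records <- function(n = 240, n_groups = 8, seed = 1) {
  # opponency depends only on the matching strata (sc_center, sc_diff),
  # never on the group label: the null of the group test
  withr::with_seed(seed, {
    sc_center <- round(runif(n, -0.6, 0.4), 1)
    sc_diff <- sample(c(0.1, 0.4, 0.7), n, replace = TRUE)
    p_opp <- 0.2 + 0.6 * (sc_diff > 0.5)
    data.frame(group_id = sample.int(n_groups, n, replace = TRUE),
               sc_center = sc_center, sc_diff = sc_diff,
               is_opponent = runif(n) < p_opp)
  })
}

test_that("group opponency test is calibrated and detects enrichment", {
  rec <- simulate_null_records(seed = 4)
  res <- group_opponency_test(rec, n_iter = 400, seed = 5)
  tested <- res[res$direction != "skipped", ]
  expect_true(all(tested$p_two_sided >= 0 & tested$p_two_sided <= 1))
  expect_true(all(tested$n_cells > 15))
  # strata-determined opponency: observed inside the null 95% interval
  rec2 <- simulate_null_records(seed = 6)
  rec2$is_opponent <- rec2$sc_diff > 0.5    # fully determined by strata
  res2 <- group_opponency_test(rec2, n_iter = 400, seed = 7)
  t2 <- res2[res2$direction != "skipped", ]
  expect_true(all(t2$p_two_sided > 0.05))
  # a group with opponency enriched beyond its strata is flagged
  rec3 <- simulate_null_records(n = 400, seed = 8)
  boost <- rec3$group_id == 1
  rec3$is_opponent[boost] <- runif(sum(boost)) < 0.95
  res3 <- group_opponency_test(rec3, n_iter = 600, seed = 9)
  g1 <- res3[res3$group_id == 1, ]
  expect_equal(g1$direction, "enriched")
  expect_lt(g1$p_two_sided, 0.05)
  # groups at or below the size threshold are skipped
  small <- rec[1:40, ]
  small$group_id <- rep(1:4, each = 10)
  res4 <- group_opponency_test(small, n_iter = 100, seed = 10)
  expect_true(all(res4$direction == "skipped"))
})
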