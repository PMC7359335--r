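test_that("robust sigma matches its closed forms", {
  expect_equal(robust_sigma(rep(0, 100)), 0)
  # alternating +/-1: median(|r|) = 1, sigma = 1 / 0.6745
  expect_equal(robust_sigma(rep(c(1, -1), 50)), 1 / 0.6745)
  # Gaussian consistency at moderate n (the 10^6 check runs in acceptance)
  z <- withr::with_seed(1, rnorm(1e5))
  expect_equal(robust_sigma(z), 1, tolerance = 0.02)
  expect_error(robust_sigma(numeric(0)), "empty")
  expect_error(robust_sigma(c(1, NA)), "finite")
})

test_that("event detection finds steps and ignores constants", {
  expect_length(detect_events(rep(1, 100), 500)$times_s, 0)
  # single upward step: exactly one event at the step sample (oracle:
  # exhaustive scan of the derivative)
  tr <- c(rep(0, 50), rep(10, 50)) + withr::with_seed(2, rnorm(100, 0, 0.5))
  d <- diff(tr) * 500
  oracle <- which(d == max(d))
  ev <- detect_events(tr, 500)
  big <- ev$indices[ev$weights > 0.5 * max(d)]
  expect_equal(big, oracle)
  # event weights are positive derivative amplitudes
  expect_true(all(ev$weights > 0))
})

test_that("events in a flicker response align with stimulus transitions", {
  prot <- make_flicker_protocol(rate_hz = 10, duration_s = 60, seed = 3)
  cell <- make_test_cell(w_center_uv = 1, polarity = "On")
  tr0 <- simulate_cell_response(cell, prot, 0, rate_hz = 11.16)
  nsd <- noise_sd_for_snr(tr0, 5)
  tr <- as.numeric(tr0) + withr::with_seed(4, rnorm(length(tr0), 0, nsd))
  prep <- preprocess_traces(matrix(tr, 1), rate_hz = 11.16)
  ev <- detect_events(prep$traces[1, ], 500)
  # recall vs the generator's transients: the prominent release events of
  # the noiseless signal (above-median derivative amplitude)
  prep0 <- preprocess_traces(matrix(as.numeric(tr0), 1), rate_hz = 11.16)
  ev0 <- detect_events(prep0$traces[1, ], 500)
  strong <- ev0$times_s[ev0$weights > median(ev0$weights)]
  hit <- vapply(strong, function(t0) any(abs(ev$times_s - t0) <= 0.15),
                logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("event-triggered kernels equal the printed average", {
  prot <- make_flicker_protocol(rate_hz = 10, duration_s = 20, seed = 5)
  # one event with weight 1: kernel equals the preceding stimulus snippet
  ev1 <- structure(list(times_s = 10, weights = 1, indices = 5000,
                        sigma = 1), class = "event_set")
  k1 <- event_triggered_kernels(ev1, prot, lag_window_s = 1)
  snippet <- prot$channels[91:101, ]
  expect_equal(unname(k1$kernels), unname(snippet), tolerance = 1e-12)
  # two events with weights (1, 3): kernel = (S1 + 3 S2) / 2
  ev2 <- structure(list(times_s = c(8, 14), weights = c(1, 3),
                        indices = c(4000, 7000), sigma = 1),
                   class = "event_set")
  k2 <- event_triggered_kernels(ev2, prot, lag_window_s = 1)
  s1 <- prot$channels[71:81, ]; s2 <- prot$channels[131:141, ]
  expect_equal(unname(k2$kernels), unname((s1 + 3 * s2) / 2),
               tolerance = 1e-12)
  # zero usable events: flagged empty
  ev0 <- structure(list(times_s = numeric(0), weights = numeric(0),
                        indices = integer(0), sigma = 0),
                   class = "event_set")
  expect_true(event_triggered_kernels(ev0, prot, 1)$empty)
})

test_that("vectorized kernels equal the naive per-event loop", {
  prot <- make_flicker_protocol(rate_hz = 10, duration_s = 30, seed = 6)
  for (s in 1:5) {
    ev <- withr::with_seed(s, {
      n <- sample(3:40, 1)
      times <- sort(runif(n, 0.5, 29.9))
      structure(list(times_s = times, weights = rexp(n), sigma = 1,
                     indices = round(times * 500)), class = "event_set")
    })
    fast <- event_triggered_kernels(ev, prot, lag_window_s = 2)
    slow <- naive_event_kernels(ev, prot, lag_window_s = 2)
    expect_lt(max(abs(fast$kernels - slow)), 1e-12)
  }
})

test_that("kernel amplitudes recover generator weights", {
  prot <- make_flicker_protocol(rate_hz = 10, duration_s = 180, seed = 7)
  # single-channel cell: UV kernel carries at least 5x the green energy
  cell <- make_test_cell(w_center_uv = -1, polarity = "Off")
  tr <- simulate_cell_response(cell, prot, 0, rate_hz = 11.16)
  prep <- preprocess_traces(matrix(as.numeric(tr), 1), rate_hz = 11.16)
  ev <- detect_events(prep$traces[1, ], 500)
  k <- event_triggered_kernels(ev, prot, 2)
  energy <- colMeans(k$kernels^2)
  expect_gt(energy[["uv_center"]], 5 * energy[["green_center"]])
  # identity-nonlinearity cell: UV:green amplitude ratio within 20%
  cell2 <- make_test_cell(w_center_uv = -0.6, w_center_green = -0.4,
                          polarity = "Off")
  tr2 <- simulate_cell_response(cell2, prot, 0, rate_hz = 11.16,
                                nonlinearity = "identity")
  prep2 <- preprocess_traces(matrix(as.numeric(tr2), 1), rate_hz = 11.16)
  k2 <- event_triggered_kernels(detect_events(prep2$traces[1, ], 500),
                                prot, 2)
  rec <- kernel_chromatic_record(k2, polarity = "Off")
  ratio <- abs(rec$f_area_uv_center / rec$f_area_green_center)
  expect_equal(ratio, 1.5, tolerance = 0.2)
  # sign pattern: both center kernels share the center polarity
  expect_equal(rec$case_center, "michelson")
})

test_that("null cells stay below the kernel quality threshold", {
  prot <- make_flicker_protocol(rate_hz = 10, duration_s = 180, seed = 8)
  qis <- unlist(lapply(1:20, function(i) {
    tr <- withr::with_seed(100 + i, rnorm(round(180 * 11.16), 0, 1))
    prep <- preprocess_traces(matrix(tr, 1), rate_hz = 11.16)
    k <- event_triggered_kernels(detect_events(prep$traces[1, ], 500),
                                 prot, 2)
    c(qi_kernel(k, "uv_center"), qi_kernel(k, "green_center"))
  }))
  expect_gte(mean(qis < 0.6), 0.95)
})

test_that("full-field event kernels average stimulus-locked snippets", {
  prot <- make_flash_protocol(n_repeats = 4, rate_hz = 100)
  rate <- 500
  n <- round(prot$duration_s * rate)
  # trace that repeats the same snippet after every UV onset
  s_uv <- prot$channels[, "uv_fullfield"]
  onsets <- which(diff(s_uv) > 0) / 100
  tr <- rep(0, n)
  bump <- 0.5 * exp(-(0:499) / 100)
  for (t0 in onsets) {
    i0 <- round(t0 * rate)
    tr[i0 + 1:500] <- bump
  }
  ek <- fullfield_event_kernels(tr, rate, prot)
  post <- ek$uv$onset$time_s > 0
  expect_equal(ek$uv$onset$kernel[post], bump[1:sum(post)], tolerance = 1e-9)
  expect_equal(ek$uv$onset$n, 4)
  # zero-mean noise: kernel amplitude shrinks with step count
  ntr <- withr::with_seed(11, rnorm(n, 0, 1))
  ekn <- fullfield_event_kernels(ntr, rate, prot)
  sem <- 1 / sqrt(4)
  expect_lt(max(abs(ekn$green$onset$kernel)), 3 * sem + 1)
  # simulated On cell: positive onset kernel, flat offset kernel
  cellOn <- make_test_cell(w_center_uv = 0.5, w_surround_uv = 0.5,
                           polarity = "On")
  trOn <- simulate_cell_response(cellOn, prot, 0, rate_hz = 7.8)
  prep <- preprocess_traces(matrix(as.numeric(trOn), 1), rate_hz = 7.8)
  ekOn <- fullfield_event_kernels(prep$traces[1, ], 500, prot)
  expect_gt(max(ekOn$uv$onset$kernel), 0.05)
  expect_gt(max(ekOn$uv$onset$kernel), 3 * max(abs(ekOn$green$onset$kernel)))
})
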