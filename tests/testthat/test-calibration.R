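test_that("simulated trials follow the balanced replicate design", {
  cal <- simulate_calibration(n_pairs = 11, replicates = 3, seed = 1)
  counts <- dplyr::count(cal, .data$pair_id, .data$distance_m,
                         .data$orientation)
  expect_true(all(counts$n == 3))
  expect_identical(nrow(cal), 11L * 7L * 2L * 3L)
  expect_true(all(cal$rssi >= propagation_params()$rssi_min))
  expect_true(all(cal$rssi <= propagation_params()$rssi_max))
})

test_that("the fit rejects singular designs", {
  cal <- simulate_calibration(seed = 1)
  expect_error(fit_propagation(cal[cal$distance_m == 1, ]), "Singular")
  one_pair <- cal[cal$pair_id == "P01", ]
  expect_error(fit_propagation(one_pair), "two pairs")
})

test_that("noise-free trials recover the curve almost exactly", {
  p0 <- propagation_params(noise_sd = 0)
  cal <- simulate_calibration(p0, pair_sd = 0, tag_sd = 0,
                              placement_sd = 0, seed = 2)
  fit <- suppressWarnings(suppressMessages(fit_propagation(cal, p = p0)))
  g <- glance(fit)
  # integer quantization is the only error source left
  expect_equal(g$slope_per_log10m, p0$slope_per_log10m, tolerance = 0.02)
})

test_that("the distance slope is recovered from design-sized trials", {
  p <- propagation_params()
  fit <- fit_propagation(simulate_calibration(p, seed = 77))
  g <- glance(fit)
  expect_lt(abs(g$slope_per_log10m - p$slope_per_log10m), 2 * g$slope_se)
  expect_lt(g$pair_sd, 5)
  ct <- tidy(fit)
  expect_true(all(c("log_distance") %in% ct$model))
  expect_identical(nrow(tidy(fit, "both")), 8L)
})

test_that("a zero orientation effect is not invented by the fit", {
  p0 <- propagation_params(orientation_penalty_max = 0)
  cover <- 0
  for (i in 1:100) {
    cal <- simulate_calibration(p0, seed = 40000 + i)
    co <- tidy(suppressWarnings(fit_propagation(cal, p = p0)))
    o <- co[co$term == "orientationperpendicular", ]
    if (abs(o$estimate) <= 2 * o$std_error) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("identical and well-separated bins are classified correctly", {
  base <- simulate_calibration(n_pairs = 4, distances_m = c(1, 2), seed = 3)
  # identical distributions: copy the 1 m readings into the 2 m bin
  same <- base
  same$rssi[same$distance_m == 2] <- same$rssi[same$distance_m == 1]
  d_same <- distance_bin_discriminability(same)
  expect_true(all(d_same$indistinguishable))

  # separation far beyond noise
  apart <- base
  apart$rssi[apart$distance_m == 2] <- apart$rssi[apart$distance_m == 2] - 200
  d_apart <- distance_bin_discriminability(apart)
  expect_false(any(d_apart$indistinguishable))
})

test_that("5 m and 10 m are the one indistinguishable pair by design", {
  hits <- list()
  for (s in 1:7) {
    d <- distance_bin_discriminability(simulate_calibration(seed = s))
    ind <- d[d$indistinguishable, , drop = FALSE]
    hits[[s]] <- paste(ind$distance_1, ind$distance_2)
  }
  counts <- table(unlist(hits))
  expect_true("5 10" %in% names(counts))
  expect_gte(counts[["5 10"]], 2)
  others <- counts[names(counts) != "5 10"]
  if (length(others)) expect_true(all(others < counts[["5 10"]]))
})

test_that("small bins are excluded from discriminability with a warning", {
  cal <- simulate_calibration(n_pairs = 3, distances_m = c(1, 2, 5), seed = 4)
  cal <- cal[!(cal$distance_m == 5 & !(cal$pair_id == "P01" &
                                         cal$replicate == 1 &
                                         cal$orientation == "parallel")), ]
  expect_warning(d <- distance_bin_discriminability(cal), "replicates")
  expect_false(5 %in% c(d$distance_1, d$distance_2))
})

test_that("maximum RSSI maps to the coarse proximity bins", {
  out <- infer_distance_bin(c(45, 3, -10))
  expect_identical(as.character(out$bin), c("<0.1m", "<5m", ">=5m"))
  # monotone: a stronger reading never maps to a farther bin
  grid <- infer_distance_bin(seq(-17, 57))
  lv <- as.integer(grid$bin)  # 1 = closest
  expect_true(all(diff(lv) <= 0))
})

test_that("the likelihood profile favours the bin the reading came from", {
  p <- propagation_params()
  fit <- fit_propagation(simulate_calibration(p, seed = 5))
  prof <- infer_distance_bin(c(50, 20, -12), fit)
  expect_equal(prof$lik_contact + prof$lik_social + prof$lik_far,
               rep(1, 3), tolerance = 1e-9)
  expect_gt(prof$lik_contact[1], prof$lik_far[1])
  expect_gt(prof$lik_far[3], prof$lik_contact[3])
})

test_that("receiver variability reports per-station spread and flags offsets", {
  p <- propagation_params()
  rec <- simulate_receiver_calibration(p, receiver_bias_sd = 0, seed = 6)
  # two identical receivers, no noise: zero coefficient of variation
  p0 <- propagation_params(noise_sd = 0)
  rec0 <- simulate_receiver_calibration(p0, n_receivers = 2,
                                        receiver_bias_sd = 0, seed = 7)
  rv0 <- receiver_variability(rec0)
  expect_equal(rv0$cv$cv, c(0, 0), tolerance = 1e-9)

  # a +10 RSSI station stands out
  rec10 <- rec0
  rec10$rssi[rec10$pair_id == "R2"] <- rec10$rssi[rec10$pair_id == "R2"] + 10L
  rv10 <- receiver_variability(rec10)
  expect_true(all(rv10$pairwise$different))

  expect_error(receiver_variability(rec0[rec0$pair_id == "R1", ]),
               "single receiver")
})

test_that("station scatter makes the far-distance CV exceed the near one", {
  bigger <- 0
  for (s in 1:10) {
    rv <- receiver_variability(
      simulate_receiver_calibration(receiver_bias_sd = 3, seed = 500 + s))
    cv <- rv$cv
    if (cv$cv[cv$distance_m == 10] > cv$cv[cv$distance_m == 1]) {
      bigger <- bigger + 1
    }
  }
  expect_gte(bigger, 8)
})
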