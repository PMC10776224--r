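test_that("habitat generation is seeded, structured, and hits the land target", {
  h1 <- make_habitat(extent_km = 20, cell_size = 100, land_fraction = 0.08,
                     seed = 5)
  h2 <- make_habitat(extent_km = 20, cell_size = 100, land_fraction = 0.08,
                     seed = 5)
  expect_identical(h1$classes, h2$classes)

  allwater <- make_habitat(land_fraction = 0, seed = 1)
  expect_true(all(allwater$water))

  got <- mean(h1$classes == 1)
  expect_lt(abs(got - 0.08) / 0.08, 0.2)
  # at least two non-land classes present, home centre on water
  expect_gte(length(setdiff(unique(as.vector(h1$classes)), 1L)), 2)
  expect_true(on_water(h1, h1$home_centre[1], h1$home_centre[2]))
  expect_error(make_habitat(extent_km = 0.5), "too small")
  expect_error(make_habitat(land_fraction = 0.6), "land_fraction")
})

test_that("OU simulation has the stationary variance and autocorrelation", {
  tau <- 300
  tr <- simulate_ou_track(NULL, sigma2 = 1e4, tau_pos = tau,
                          duration_s = 2000 * tau, dt_s = 30, seed = 8)
  emp_var <- (var(tr$x) + var(tr$y)) / 2
  expect_lt(abs(emp_var - 1e4) / 1e4, 0.05)
  lag <- tau / 30
  acx <- acf(tr$x, lag.max = lag, plot = FALSE)$acf[lag + 1]
  acy <- acf(tr$y, lag.max = lag, plot = FALSE)$acf[lag + 1]
  expect_lt(abs((acx + acy) / 2 - exp(-1)), 0.05)
})

test_that("a near-zero variance track stays at the home centre", {
  tr <- simulate_ou_track(NULL, sigma2 = 1e-6, tau_pos = 600,
                          duration_s = 6000, dt_s = 60,
                          home = c(5000, 7000), seed = 2)
  expect_lt(max(abs(tr$x - 5000)), 0.5)
  expect_lt(max(abs(tr$y - 7000)), 0.5)
})

test_that("OUF simulation keeps the stationary position variance and is smoother", {
  tr <- simulate_ou_track(NULL, sigma2 = 1e4, tau_pos = 600, tau_vel = 60,
                          duration_s = 600 * 800, dt_s = 30, seed = 9)
  emp_var <- (var(tr$x) + var(tr$y)) / 2
  expect_lt(abs(emp_var - 1e4) / 1e4, 0.15)
  # velocity autocorrelation: one-step displacement correlation is positive
  dx <- diff(tr$x)
  expect_gt(cor(dx[-1], dx[-length(dx)]), 0.2)
  expect_error(simulate_ou_track(NULL, sigma2 = 1, tau_pos = 100,
                                 tau_vel = 200, duration_s = 1000),
               "tau_vel")
})

test_that("tracks are confined to water and reject land home centres", {
  hab <- small_habitat()
  land_cell <- which(!hab$water, arr.ind = TRUE)[1, ]
  cc <- cell_centres(hab$grid)
  expect_error(simulate_ou_track(hab, sigma2 = 1e4, tau_pos = 600,
                                 duration_s = 600,
                                 home = c(cc$x[land_cell[2]],
                                          cc$y[land_cell[1]])),
               "land")
  tr <- simulate_ou_track(hab, sigma2 = 2.5e5, tau_pos = 3600,
                          duration_s = 86400, dt_s = 60, seed = 4)
  expect_true(all(on_water(hab, tr$x, tr$y)))
})

test_that("receiver placement is seeded, on water, and carries kernel classes", {
  hab <- small_habitat()
  r1 <- place_receivers(hab, 63, "random", seed = 6)
  r2 <- place_receivers(hab, 63, "random", seed = 6)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 63)
  expect_true(all(on_water(hab, r1$x, r1$y)))
  expect_true(all(r1$kernel_class %in% c("reef", "sand")))
  expect_true(all(r1$kernel_class[r1$habitat_class %in%
                                    c("reef", "seagrass")] == "reef"))
})

test_that("grid receiver placement is near-uniform on open water", {
  hab <- make_habitat(extent_km = 10, cell_size = 100, land_fraction = 0,
                      seed = 1)
  r <- place_receivers(hab, 49, "grid", seed = 1)
  nn <- vapply(seq_len(49), function(i) {
    d <- sqrt((r$x - r$x[i])^2 + (r$y - r$y[i])^2)
    min(d[-i])
  }, numeric(1))
  expect_lt(sd(nn) / mean(nn), 0.2)
})

test_that("range tests draw binomial detections under the kernel", {
  k <- reef_kernel()
  rt <- simulate_range_test(k, c(0, 185, 520), n_per_distance = 1000, seed = 3)
  p0 <- kernel_prob(k, 0)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(rt$n_detected[2] / 1000 - 0.5), 3 * se)
  expect_lt(abs(rt$n_detected[1] / 1000 - p0),
            3 * sqrt(p0 * (1 - p0) / 1000) + 1e-3)
  expect_error(simulate_range_test(k, c(-10, 0), 100), ">= 0")
  expect_error(simulate_range_test(k, c(0, 250), 0), "n_per_distance")
})

test_that("acoustic detections follow the transmission schedule and kernel", {
  k <- both_kernels()
  recv <- data.frame(receiver_id = "R001", x = 0, y = 0,
                     habitat_class = "reef", kernel_class = "reef")
  # animal parked on the receiver: detections/day ~ (86400/90) * p(0)
  tr0 <- simulate_ou_track(NULL, sigma2 = 1e-6, tau_pos = 600,
                           duration_s = 5 * 86400, dt_s = 300, seed = 11)
  det <- simulate_acoustic_detections(tr0, recv, k, seed = 12)
  n_tx_expected <- 5 * 86400 / 90
  p0 <- kernel_prob(k$reef, 0)
  rate <- nrow(det) / n_tx_expected
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / n_tx_expected) + 0.01)

  # animal far beyond the 1% range: silence
  trf <- simulate_ou_track(NULL, sigma2 = 1e2, tau_pos = 600,
                           duration_s = 86400, dt_s = 300,
                           home = c(50000, 0), seed = 13)
  expect_equal(nrow(simulate_acoustic_detections(trf, recv, k, seed = 14)), 0)

  # no receivers: empty table
  expect_equal(nrow(simulate_acoustic_detections(tr0, recv[0, ], k)), 0)
})

test_that("transmission count matches the mean uniform delay", {
  recv <- data.frame(receiver_id = "R001", x = 0, y = 0,
                     habitat_class = "reef", kernel_class = "reef")
  # a perfect kernel isolates the transmission schedule
  perfect <- detection_kernel(30, -0.001, "reef")
  tr0 <- simulate_ou_track(NULL, sigma2 = 1e-6, tau_pos = 600,
                           duration_s = 10 * 86400, dt_s = 600, seed = 21)
  det <- simulate_acoustic_detections(tr0, recv, list(reef = perfect), seed = 22)
  per_day <- nrow(det) / 10
  expect_lt(abs(per_day - 960) / 960, 0.05)
})

test_that("Argos fixes carry class frequencies and class-dependent errors", {
  tr <- simulate_ou_track(NULL, sigma2 = 1e4, tau_pos = 3600,
                          duration_s = 86400 * 800, dt_s = 3600, seed = 15)
  fx <- simulate_argos_fixes(tr, fixes_per_day = 2.5, seed = 16)
  n <- nrow(fx)
  probs <- default_class_probs()
  freq <- table(factor(fx$lc, levels = names(probs))) / n
  for (cl in names(probs)) {
    se <- sqrt(probs[cl] * (1 - probs[cl]) / n)
    expect_lt(abs(freq[cl] - probs[cl]), 3 * se + 1e-3)
  }
  # per-class empirical error sd within 10% at n ~ 2000
  truth <- trackcompare:::track_position_at(tr, as.numeric(fx$timestamp) -
                               as.numeric(tr$time[1]))
  err <- sqrt((fx$x - truth$x)^2 + (fx$y - truth$y)^2)
  sds <- default_class_sds()
  for (cl in c("A", "B")) {
    sel <- fx$lc == cl
    emp <- sqrt(mean(err[sel]^2) / 2)  # isotropic: per-axis sd
    expect_lt(abs(emp - sds[cl]) / sds[cl], 0.1)
  }

  zero <- simulate_argos_fixes(tr, class_sd_m = setNames(rep(0, 7),
                                                         names(sds)),
                               seed = 17)
  tz <- trackcompare:::track_position_at(tr, as.numeric(zero$timestamp) -
                            as.numeric(tr$time[1]))
  expect_lt(max(abs(zero$x - tz$x), abs(zero$y - tz$y)), 1e-6)

  bad_probs <- probs; bad_probs["B"] <- 0.9
  expect_error(simulate_argos_fixes(tr, class_probs = bad_probs), "sum to 1")
  expect_error(simulate_argos_fixes(tr, class_probs = c(`3` = 1)),
               "cover classes")
  bad_sds <- sds; bad_sds["B"] <- -1
  expect_error(simulate_argos_fixes(tr, class_sd_m = bad_sds), ">= 0")
})

test_that("generators are bit-reproducible under a fixed seed", {
  hab <- small_habitat()
  tr1 <- simulate_ou_track(hab, sigma2 = 2.5e5, tau_pos = 3600,
                           duration_s = 43200, dt_s = 60, seed = 30)
  tr2 <- simulate_ou_track(hab, sigma2 = 2.5e5, tau_pos = 3600,
                           duration_s = 43200, dt_s = 60, seed = 30)
  expect_identical(tr1$x, tr2$x)
  recv <- place_receivers(hab, 20, seed = 31)
  d1 <- simulate_acoustic_detections(tr1, recv, both_kernels(), seed = 32)
  d2 <- simulate_acoustic_detections(tr2, recv, both_kernels(), seed = 32)
  expect_identical(d1, d2)
  a1 <- simulate_argos_fixes(tr1, seed = 33)
  a2 <- simulate_argos_fixes(tr2, seed = 33)
  expect_identical(a1, a2)
})
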