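make_detections <- function(times, tag = "A", receiver = "R001") {
  data.frame(tag_id = tag, receiver_id = receiver,
             timestamp = utc("2017-05-02 00:00:00") + times,
             stringsAsFactors = FALSE)
}
std_deploy <- data.frame(tag_id = "A",
                         release_time = as.POSIXct("2017-05-02 00:00:00",
                                                   tz = "UTC"),
                         x = 0, y = 0)

test_that("detection filtering applies each rule in order and reports counts", {
  day <- 86400
  d <- make_detections(c(day + 3600, day + 3600,      # duplicate pair
                         -100,                        # pre-release
                         1800,                        # within 24 h
                         day + 5000, day + 6000,      # close pair, kept
                         day + 12 * 3600))            # lone (>1 h gap)
  out <- filter_detections(d, std_deploy)
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep["duplicates"]), 1L)
  expect_equal(unname(rep["pre_release"]), 1L)
  expect_equal(unname(rep["acclimation"]), 1L)
  # the dup survivor at +1h sits 1400 s before the close pair, so only the
  # isolated 12 h detection is lone
  expect_equal(unname(rep["lone"]), 1L)
  expect_equal(nrow(out), 3)

  # two detections 30 min apart, past 24 h, no blackout: both kept
  d2 <- make_detections(c(day + 1000, day + 2800))
  expect_equal(nrow(filter_detections(d2, std_deploy)), 2)

  # a single detection 3 h from its nearest same-tag neighbour is removed
  d3 <- make_detections(c(day + 1000, day + 2000, day + 2000 + 3 * 3600))
  expect_equal(nrow(filter_detections(d3, std_deploy)), 2)
})

test_that("blackout windows excise detections and filtering is idempotent", {
  day <- 86400
  blk <- data.frame(start = utc("2017-05-04 00:00:00"),
                    end = utc("2017-05-06 09:00:00"))  # 57 h
  d <- make_detections(c(day + 1000, day + 2000,
                         2.5 * day, 2.5 * day + 600))  # inside the blackout
  out <- filter_detections(d, std_deploy, blk)
  expect_equal(unname(attr(out, "filter_report")["blackout"]), 2L)
  expect_equal(nrow(out), 2)
  twice <- filter_detections(out, std_deploy, blk)
  expect_equal(twice, out, ignore_attr = TRUE)
  expect_true(all(attr(twice, "filter_report") == 0))
})

test_that("unknown tags are rejected with their ids", {
  d <- make_detections(1000, tag = "ZZ")
  expect_error(filter_detections(d, std_deploy), "ZZ")
})

test_that("the two-point kernel solution matches the analytic 2x2 system", {
  k <- kernel_from_ranges(185, 520, "reef")
  expect_equal(k$b, -log(99) / 335, tolerance = 1e-12)
  expect_equal(k$a, 185 * log(99) / 335, tolerance = 1e-12)
  expect_equal(k$b, -0.013717, tolerance = 1e-4)
  expect_equal(k$a, 2.5376, tolerance = 1e-4)
  expect_equal(kernel_prob(k, k$d50), 0.5, tolerance = 1e-12)
  expect_equal(kernel_prob(k, k$d01), 0.01, tolerance = 1e-10)
})

test_that("logistic kernel fitting recovers d50 and honours p(d50) = 0.5", {
  rt <- simulate_range_test(reef_kernel(), c(0, 250, 500, 750),
                            n_per_distance = 1000, seed = 19)
  fit <- fit_detection_kernel(rt, "reef")
  expect_lt(abs(fit$d50 - 185) / 185, 0.10)
  expect_equal(kernel_prob(fit, fit$d50), 0.5, tolerance = 1e-12)

  expect_error(fit_detection_kernel(
    data.frame(distance_m = 100, n_expected = 50, n_detected = 10)),
    "2 distinct distances")
  expect_error(fit_detection_kernel(
    data.frame(distance_m = c(0, 100), n_expected = 50, n_detected = 0)),
    "all-zero")
})

test_that("relocation radii follow the area-weighted kernel density", {
  k <- reef_kernel()
  recv <- data.frame(receiver_id = "R001", x = 0, y = 0,
                     habitat_class = "reef", kernel_class = "reef")
  det <- make_detections(seq_len(20000) * 60)
  rel <- relocate_detections(det, recv, list(reef = k), habitat = NULL,
                             seed = 23)
  expect_true(all(rel$radius_m <= k$d01))
  # quadrature oracle for the mean radius of density ~ d p(d) on [0, d01]
  num <- integrate(function(d) d^2 * kernel_prob(k, d), 0, k$d01)$value
  den <- integrate(function(d) d * kernel_prob(k, d), 0, k$d01)$value
  expect_lt(abs(mean(rel$radius_m) - num / den) / (num / den), 0.02)
  # consistency of the stored radius with the sampled position
  expect_equal(sqrt(rel$x^2 + rel$y^2), rel$radius_m, tolerance = 1e-9)
})

test_that("relocated detections avoid land and respect the redraw cap", {
  hab <- small_habitat()
  recv <- place_receivers(hab, 10, seed = 24)
  det <- do.call(rbind, lapply(recv$receiver_id, function(r)
    make_detections(seq_len(50) * 60, receiver = r)))
  rel <- relocate_detections(det, recv, both_kernels(), hab, seed = 25)
  expect_true(all(on_water(hab, rel$x, rel$y)))
  expect_error(relocate_detections(det, recv, list(), hab),
               "no detection kernel")
})

test_that("COAs are clock-binned means with receiver-distance error radii", {
  # one detection 120 m from its receiver
  one <- data.frame(tag_id = "A", receiver_id = "R001",
                    timestamp = utc("2017-05-02 10:05:00"),
                    x = 120, y = 0, radius_m = 120)
  coa1 <- compute_coas(one)
  expect_equal(coa1$x, 120)
  expect_equal(coa1$error_radius_m, 120)
  expect_equal(coa1$n_detections, 1L)
  expect_equal(format(coa1$time, "%H:%M", tz = "UTC"), "10:15")

  # three relocations averaged within one bin
  three <- data.frame(tag_id = "A", receiver_id = "R001",
                      timestamp = utc("2017-05-02 10:05:00") + c(0, 60, 120),
                      x = c(0, 2, 4), y = 0, radius_m = c(10, 20, 30))
  coa3 <- compute_coas(three)
  expect_equal(nrow(coa3), 1)
  expect_equal(coa3$x, 2)
  expect_equal(coa3$error_radius_m, 20)

  # 10:05 and 10:35 split into two bins; 10:05 and 10:20 share one
  split2 <- data.frame(tag_id = "A", receiver_id = "R001",
                       timestamp = utc("2017-05-02 10:05:00") + c(0, 1800),
                       x = 0, y = 0, radius_m = 1)
  expect_equal(nrow(compute_coas(split2)), 2)
  share <- data.frame(tag_id = "A", receiver_id = "R001",
                      timestamp = utc("2017-05-02 10:05:00") + c(0, 900),
                      x = 0, y = 0, radius_m = 1)
  expect_equal(nrow(compute_coas(share)), 1)
  expect_equal(nrow(compute_coas(share[0, ])), 0)
})

test_that("a degenerate kernel collapses COAs onto the receiver", {
  tiny <- kernel_from_ranges(1, 2, "reef")  # d01 = 2 m
  recv <- data.frame(receiver_id = "R001", x = 1000, y = 2000,
                     habitat_class = "reef", kernel_class = "reef")
  det <- make_detections(seq_len(200) * 60)
  rel <- relocate_detections(det, recv, list(reef = tiny), seed = 26)
  coas <- compute_coas(rel)
  expect_lt(max(sqrt((coas$x - 1000)^2 + (coas$y - 2000)^2)), 2)
  expect_lt(max(coas$error_radius_m), 2)
})

test_that("COA counts are bounded by bins and detections", {
  set.seed(27)
  n <- 500
  rel <- data.frame(tag_id = "A", receiver_id = "R001",
                    timestamp = utc("2017-05-02 00:00:00") +
                      sort(runif(n, 0, 5 * 86400)),
                    x = rnorm(n), y = rnorm(n), radius_m = abs(rnorm(n, 100)))
  coas <- compute_coas(rel)
  expect_lte(nrow(coas), n)
  bins <- length(unique(floor(as.numeric(rel$timestamp) / 1800)))
  expect_equal(nrow(coas), bins)
})

test_that("COAs centre on the receiver, not the animal (documented bias)", {
  # stationary animal 150 m from a receiver: relocations are centred on the
  # receiver, so the mean COA sits near the receiver rather than the animal
  k <- reef_kernel()
  recv <- data.frame(receiver_id = "R001", x = 0, y = 0,
                     habitat_class = "reef", kernel_class = "reef")
  det <- make_detections(seq_len(5000) * 60)
  rel <- relocate_detections(det, recv, list(reef = k), seed = 28)
  coas <- compute_coas(rel)
  mean_pos <- c(mean(coas$x), mean(coas$y))
  kernel_sd <- sd(rel$radius_m)
  expect_lt(sqrt(sum(mean_pos^2)), kernel_sd)
})
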