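test_that("the bridge positional variance matches its closed form", {
  # T = 1800 s, sigma_m2 = 0.02, endpoint errors 50 m, midpoint:
  # 9 + 625 + 625 = 1259 m^2
  expect_equal(bb_variance(0.5, 1800, 0.02, 50, 50), 1259)
  expect_equal(bb_variance(0, 1800, 0.02, 50, 70), 2500)
  expect_equal(bb_variance(1, 1800, 0.02, 50, 70), 4900)
})

test_that("motion variance is zero for a stationary errorless track", {
  n <- 9
  expect_lt(estimate_motion_variance(rep(3, n), rep(4, n), (0:(n - 1)) * 60,
                                     0), 1e-6)
})

test_that("the motion-variance optimizer matches a brute-force grid search", {
  grid <- exp(seq(log(1e-6), log(1e3), length.out = 1000))
  for (seed in 1:10) {
    tr <- bm_track(n = 40, sigma_m2 = 10^runif(1, -3, 1), noise = 20,
                   seed = seed)
    est <- estimate_motion_variance(tr$x, tr$y, tr$t, 20)
    bt <- trackcompare:::bridge_terms(tr$x, tr$y, tr$t, rep(20, 40))
    ll <- vapply(grid, trackcompare:::bridge_loglik, numeric(1), bt = bt)
    best <- grid[which.max(ll)]
    # within one grid step (log-spaced) of the brute-force optimum
    step <- log(grid[2] / grid[1])
    expect_lt(abs(log(max(est, 1e-6)) - log(best)), 1.5 * step + 1e-9)
  }
})

test_that("motion variance scales quadratically with coordinates", {
  tr <- bm_track(n = 60, sigma_m2 = 0.1, noise = 10, seed = 3)
  base <- estimate_motion_variance(tr$x, tr$y, tr$t, 10)
  for (c in c(0.5, 3)) {
    scaled <- estimate_motion_variance(c * tr$x, c * tr$y, tr$t, c * 10)
    expect_lt(abs(scaled - c^2 * base) / (c^2 * base), 1e-3)
  }
})

test_that("segmentation keeps a single variance on homogeneous tracks", {
  cfg <- dbbmm_config()
  hits <- 0; total <- 0
  for (seed in 1:20) {
    tr <- bm_track(n = 200, sigma_m2 = 0.05, noise = 0, seed = 100 + seed)
    prof <- dynamic_segmentation(tr$x, tr$y, tr$t, 0, cfg)
    n_win <- 200 - cfg$window + 1
    hits <- hits + (n_win - length(prof$breakpoints))
    total <- total + n_win
  }
  expect_gte(hits / total, 0.9)
})

test_that("segmentation localizes a 25x variance change", {
  cfg <- dbbmm_config(window = 31, margin = 9, min_locations = 31)
  found <- 0
  for (seed in 1:20) {
    set.seed(200 + seed)
    n <- 120; dt <- 1800; t <- (0:(n - 1)) * dt
    s <- c(rep(0.01, n / 2), rep(0.25, n / 2))
    x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s[-1] * dt))))
    y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s[-1] * dt))))
    prof <- dynamic_segmentation(x, y, t, 0, cfg)
    if (any(abs(prof$breakpoints - n / 2) <= cfg$window / 2)) found <- found + 1
    # profile reflects the change in level
    expect_gt(mean(prof$sigma_m2[(n / 2 + 16):n]),
              mean(prof$sigma_m2[1:(n / 2 - 16)]))
  }
  expect_gte(found, 16)
})

test_that("a track exactly one window long still gets a full profile", {
  cfg <- dbbmm_config(window = 31, margin = 9, min_locations = 31)
  tr <- bm_track(n = 31, seed = 5)
  prof <- dynamic_segmentation(tr$x, tr$y, tr$t, 0, cfg)
  expect_length(prof$sigma_m2, 31)
  expect_true(all(is.finite(prof$sigma_m2)))
  # shorter than the window: single global value
  tr2 <- bm_track(n = 20, seed = 6)
  prof2 <- dynamic_segmentation(tr2$x, tr2$y, tr2$t, 0, cfg)
  expect_equal(length(unique(prof2$sigma_m2)), 1)
})

test_that("bridge densities normalize, localize, and respect gaps", {
  # degenerate bridge: two coincident fixes, tiny error
  prof <- structure(list(sigma_m2 = c(1e-8, 1e-8), breakpoints = integer(0)),
                    class = "motion_variance_profile")
  cfg <- dbbmm_config(window = 3, margin = 1, cell_size = 50,
                      min_locations = 2, time_substeps = 5)
  # position at a cell centre so the whole bridge falls in one cell
  s <- bridge_density(c(1025, 1025), c(1025, 1025), c(0, 600), c(1, 1),
                      prof, cfg)
  expect_lt(abs(sum(s$density) - 1), 1e-9)
  idx <- which(s$density == max(s$density), arr.ind = TRUE)
  cc <- cell_centres(s$grid)
  expect_lt(abs(cc$x[idx[2]] - 1025), 50)
  expect_gt(max(s$density), 0.99)

  # a 30 h gap is not bridged under the 24 h rule
  tr <- bm_track(n = 60, sigma_m2 = 0.02, seed = 7)
  t_gap <- tr$t; t_gap[31:60] <- t_gap[31:60] + 30 * 3600
  x <- tr$x; x[31:60] <- x[31:60] + 20000  # far-away second burst
  profg <- structure(list(sigma_m2 = rep(0.02, 60), breakpoints = integer(0)),
                     class = "motion_variance_profile")
  g <- grid_spec(min(x) - 2000, min(tr$y) - 2000, 200,
                 ceiling((diff(range(tr$y)) + 4000) / 200),
                 ceiling((diff(range(x)) + 4000) / 200))
  s24 <- bridge_density(x, tr$y, t_gap, 10, profg, cfg, g)
  sInf <- bridge_density(x, tr$y, t_gap, 10, profg,
                         dbbmm_config(window = 3, margin = 1, cell_size = 50,
                                      min_locations = 2, time_substeps = 5,
                                      gap_threshold_s = Inf), g)
  # mass midway between the bursts only appears when the gap is bridged
  mid_cols <- which(abs(cell_centres(g)$x - (mean(range(x)))) < 5000)
  expect_lt(sum(s24$density[, mid_cols]), 1e-6)
  expect_gt(sum(sInf$density[, mid_cols]), 0.1)

  expect_error(bridge_density(c(0, 10), c(0, 0), c(0, 200000), 1, prof, cfg),
               "no valid bridge")
})

test_that("with a single variance the dynamic estimate equals a static bridge", {
  tr <- bm_track(n = 40, sigma_m2 = 0.05, noise = 15, seed = 8)
  cfg <- dbbmm_config(window = 49, margin = 15, cell_size = 100,
                      min_locations = 10, time_substeps = 10)
  od <- estimate_od(data.frame(t = tr$t, x = tr$x, y = tr$y, error = 15), cfg)
  # independent static construction: one global variance, direct quadrature
  s2 <- estimate_motion_variance(tr$x, tr$y, tr$t, 15)
  expect_equal(unique(od$profile$sigma_m2), s2)
  g <- od$surface$grid
  gl <- pracma::gaussLegendre(10, 0, 1)
  xe <- g$origin_x + (0:g$n_cols) * g$cell_size
  ye <- g$origin_y + (0:g$n_rows) * g$cell_size
  dens <- matrix(0, g$n_rows, g$n_cols)
  for (i in 1:39) {
    TT <- tr$t[i + 1] - tr$t[i]
    for (q in 1:10) {
      a <- gl$x[q]
      mx <- (1 - a) * tr$x[i] + a * tr$x[i + 1]
      my <- (1 - a) * tr$y[i] + a * tr$y[i + 1]
      sd <- sqrt(bb_variance(a, TT, s2, 15, 15))
      dens <- dens + gl$w[q] * TT *
        (diff(pnorm(ye, my, sd)) %o% diff(pnorm(xe, mx, sd)))
    }
  }
  dens <- dens / sum(dens)
  expect_lt(sum(abs(dens - od$surface$density)), 1e-6)
})

test_that("occurrence distributions respect sample-size and nesting rules", {
  tr <- bm_track(n = 48, seed = 9)
  cfg <- dbbmm_config()  # min_locations 49
  expect_error(estimate_od(data.frame(t = tr$t, x = tr$x, y = tr$y,
                                      error = 10), cfg),
               "insufficient data: 48")
  tr2 <- bm_track(n = 60, sigma_m2 = 0.05, noise = 20, seed = 10)
  cfg2 <- dbbmm_config(window = 31, margin = 9, cell_size = 100,
                       min_locations = 31)
  od <- estimate_od(data.frame(t = tr2$t, x = tr2$x, y = tr2$y, error = 20),
                    cfg2)
  k50 <- paste(od$regions[["0.5"]]$rows, od$regions[["0.5"]]$cols)
  k95 <- paste(od$regions[["0.95"]]$rows, od$regions[["0.95"]]$cols)
  expect_true(all(k50 %in% k95))
  # all-water: clipped and unclipped areas agree
  expect_equal(od$areas$area_km2, od$areas$area_unclipped_km2)
})

test_that("larger location errors never shrink the 95% area", {
  cfg <- dbbmm_config(window = 31, margin = 9, cell_size = 100,
                      min_locations = 31)
  for (seed in 1:10) {
    tr <- bm_track(n = 50, sigma_m2 = 0.05, seed = 300 + seed)
    g <- grid_spec(min(tr$x) - 4000, min(tr$y) - 4000, 100,
                   ceiling((diff(range(tr$y)) + 8000) / 100),
                   ceiling((diff(range(tr$x)) + 8000) / 100))
    a1 <- estimate_od(data.frame(t = tr$t, x = tr$x, y = tr$y, error = 50),
                      cfg, grid = g)$areas$area_km2[1]
    a2 <- estimate_od(data.frame(t = tr$t, x = tr$x, y = tr$y, error = 100),
                      cfg, grid = g)$areas$area_km2[1]
    expect_gte(a2, a1)
  }
})

test_that("doubling the quadrature nodes barely changes areas", {
  tr <- bm_track(n = 60, sigma_m2 = 0.05, noise = 20, seed = 11)
  locs <- data.frame(t = tr$t, x = tr$x, y = tr$y, error = 20)
  g <- grid_spec(min(tr$x) - 3000, min(tr$y) - 3000, 100,
                 ceiling((diff(range(tr$y)) + 6000) / 100),
                 ceiling((diff(range(tr$x)) + 6000) / 100))
  a10 <- estimate_od(locs, dbbmm_config(window = 31, margin = 9,
                                        min_locations = 31,
                                        time_substeps = 10), grid = g)$areas
  a20 <- estimate_od(locs, dbbmm_config(window = 31, margin = 9,
                                        min_locations = 31,
                                        time_substeps = 20), grid = g)$areas
  expect_lt(max(abs(a20$area_km2 - a10$area_km2) / a10$area_km2), 0.005)
})

test_that("land clipping removes region cells without renormalizing", {
  hab <- small_habitat()
  home <- hab$home_centre
  tr <- simulate_ou_track(hab, sigma2 = 4e5, tau_pos = 2 * 3600,
                          duration_s = 86400 * 2, dt_s = 1800, seed = 12)
  locs <- data.frame(t = tr$t, x = tr$x, y = tr$y, error = 100)
  cfg <- dbbmm_config(window = 31, margin = 9, cell_size = 100,
                      min_locations = 31)
  od <- estimate_od(locs, cfg, habitat = hab)
  expect_lte(od$areas$area_km2[1], od$areas$area_unclipped_km2[1])
  wm <- water_mask_on_grid(hab, od$surface$grid)
  expect_true(all(od$surface$density[!wm] == 0))
})
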