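# Shared fixtures, built in code at test time.

reef_kernel <- function() kernel_from_ranges(185, 520, "reef")
sand_kernel <- function() kernel_from_ranges(350, 1100, "sand")
both_kernels <- function() list(reef = reef_kernel(), sand = sand_kernel())

# small Brownian-motion track with optional observation noise
bm_track <- function(n = 200, dt = 1800, sigma_m2 = 0.05, noise = 0, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) * dt
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma_m2 * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma_m2 * dt))))
  list(t = t, x = x + rnorm(n, 0, noise), y = y + rnorm(n, 0, noise))
}

# tiny Gaussian probability surface for overlap tests
gaussian_surface <- function(cx, cy, sd, grid) {
  xe <- grid$origin_x + (0:grid$n_cols) * grid$cell_size
  ye <- grid$origin_y + (0:grid$n_rows) * grid$cell_size
  d <- diff(pnorm(ye, cy, sd)) %o% diff(pnorm(xe, cx, sd))
  probability_surface(grid, d / sum(d))
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

small_habitat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_habitat(extent_km = 10, cell_size = 100,
                                               land_fraction = 0.1, seed = 42)
    cache
  }
})
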