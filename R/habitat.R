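#' Synthetic two-island lagoon habitat
#'
#' Generates a habitat grid emulating a small-island system: two elongated
#' islands meeting at a corner with a semi-enclosed shallow lagoon between
#' them, a fringing reef band along island shores, a seagrass bed south of the
#' southern island, and open sand elsewhere. Island outlines carry smooth
#' seeded noise so shorelines are irregular but reproducible.
#'
#' @param extent_km grid extent (square) in km.
#' @param cell_size cell edge (m).
#' @param land_fraction target fraction of cells that are land, in \[0, 0.5).
#' @param seed integer seed; the same seed always yields the same grid.
#' @return object of class `habitat_grid`: `grid` ([grid_spec()]), integer
#'   `classes` matrix with levels land/reef/seagrass/sand/lagoon, logical
#'   `water` matrix, and `home_centre` (planar m) inside the lagoon.
#' @export
make_habitat <- function(extent_km = 20, cell_size = 100,
                         land_fraction = 0.08, seed = 1) {
  if (land_fraction < 0 || land_fraction >= 0.5) {
    stop("land_fraction must be in [0, 0.5)")
  }
  if (extent_km * 1000 < 20 * cell_size) {
    stop("extent too small for the requested habitat structure")
  }
  n <- as.integer(round(extent_km * 1000 / cell_size))
  g <- grid_spec(0, 0, cell_size, n, n, crs_note = "synthetic planar metres")
  cc <- cell_centres(g)
  ext <- extent_km * 1000
  u <- matrix(rep(cc$x / ext, each = n), n, n)   # [row, col]: x normalized
  v <- matrix(rep(cc$y / ext, times = n), n, n)  # y normalized

  # smooth seeded noise field for shoreline irregularity
  set.seed(seed)
  coarse <- matrix(stats::rnorm(81, sd = 1), 9, 9)
  noise <- bilinear_expand(coarse, n)

  # two islands in an L: one running north-south, one west-east
  ell <- function(cx, cy, ax, ay, s) {
    ((u - cx) / (ax * s))^2 + ((v - cy) / (ay * s))^2
  }
  island_mask <- function(s) {
    d1 <- ell(0.40, 0.58, 0.035, 0.16, s)
    d2 <- ell(0.55, 0.38, 0.16, 0.035, s)
    (d1 + 0.35 * noise < 1) | (d2 + 0.35 * noise < 1)
  }
  land <- matrix(FALSE, n, n)
  if (land_fraction > 0) {
    s <- 1
    for (i in 1:3) {  # scale island axes toward the requested land fraction
      land <- island_mask(s)
      got <- mean(land)
      if (got <= 0) { s <- s * 2; next }
      s <- s * sqrt(land_fraction / got)
    }
    land <- island_mask(s)
  }

  # lagoon: water near the concave corner of the L, opening to the north-east
  corner <- c(0.47, 0.47)
  lagoon <- !land &
    sqrt((u - corner[1])^2 + (v - corner[2])^2) < 0.14 &
    (u > 0.40) & (v > 0.36)
  # fringing reef: water within ~2 cells of land, outside the lagoon
  near_land <- if (any(land)) dilate_mask(land, 2) & !land else matrix(FALSE, n, n)
  reef <- near_land & !lagoon
  seagrass <- !land & !lagoon & !reef & v < 0.30 & u > 0.30 & u < 0.80

  lv <- c("land", "reef", "seagrass", "sand", "lagoon")
  classes <- matrix(4L, n, n)  # sand
  classes[seagrass] <- 3L
  classes[reef] <- 2L
  classes[lagoon] <- 5L
  classes[land] <- 1L

  home <- corner * ext
  if (land_fraction > 0 && classes[pos_to_cell(g, home[1], home[2])] == 1L) {
    # fall back to the nearest lagoon/water cell
    w <- which(classes != 1L, arr.ind = TRUE)
    d2 <- (cc$y[w[, 1]] - home[2])^2 + (cc$x[w[, 2]] - home[1])^2
    k <- which.min(d2)
    home <- c(cc$x[w[k, 2]], cc$y[w[k, 1]])
  }

  structure(list(grid = g, classes = classes, levels = lv,
                 water = classes != 1L, home_centre = home, seed = seed),
            class = "habitat_grid")
}

bilinear_expand <- function(coarse, n) {
  nc <- nrow(coarse)
  at <- seq(1, nc, length.out = n)
  i0 <- pmin(floor(at), nc - 1); f <- at - i0
  row_interp <- coarse[i0, , drop = FALSE] * (1 - f) +
    coarse[i0 + 1, , drop = FALSE] * f
  row_interp[, i0, drop = FALSE] * rep(1 - f, each = n) +
    row_interp[, i0 + 1, drop = FALSE] * rep(f, each = n)
}

dilate_mask <- function(m, k) {
  out <- m
  n1 <- nrow(m); n2 <- ncol(m)
  for (di in -k:k) for (dj in -k:k) {
    if (di == 0 && dj == 0) next
    src_i <- max(1, 1 - di):min(n1, n1 - di)
    src_j <- max(1, 1 - dj):min(n2, n2 - dj)
    out[src_i + di, src_j + dj] <- out[src_i + di, src_j + dj] | m[src_i, src_j]
  }
  out
}

#' @export
print.habitat_grid <- function(x, ...) {
  tab <- table(factor(x$levels[x$classes], levels = x$levels))
  cat(sprintf("habitat_grid: %d x %d cells of %g m\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size))
  print(round(tab / length(x$classes), 3))
  invisible(x)
}

#' @export
plot.habitat_grid <- function(x, ...) {
  cc <- cell_centres(x$grid)
  cols <- c("khaki4", "coral3", "darkgreen", "lightyellow2", "lightblue2")
  graphics::image(cc$x, cc$y, t(x$classes), col = cols, useRaster = TRUE,
                  xlab = "easting (m)", ylab = "northing (m)", ...)
  invisible(x)
}

# row/col lookup for a planar position; positions outside the grid get NA
pos_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row, col)
}

#' Water test for planar positions
#'
#' Positions outside the habitat grid count as open water.
#'
#' @param habitat a [make_habitat()] result, or NULL (everything is water).
#' @param x,y planar coordinates (m).
#' @return logical vector.
#' @export
on_water <- function(habitat, x, y) {
  if (is.null(habitat)) return(rep(TRUE, length(x)))
  idx <- pos_to_cell(habitat$grid, x, y)
  out <- rep(TRUE, length(x))
  ok <- !is.na(idx[, 1])
  out[ok] <- habitat$water[idx[ok, , drop = FALSE]]
  out
}

#' Water mask of a habitat resampled onto an analysis grid
#'
#' Nearest-neighbour (cell centre) lookup; target cells outside the habitat
#' extent are treated as water.
#'
#' @param habitat a [make_habitat()] result or NULL.
#' @param grid target [grid_spec()]; NULL returns the habitat's own mask.
#' @return logical matrix on `grid`.
#' @export
water_mask_on_grid <- function(habitat, grid = NULL) {
  if (is.null(habitat)) {
    stopifnot(!is.null(grid))
    return(matrix(TRUE, grid$n_rows, grid$n_cols))
  }
  if (is.null(grid)) return(habitat$water)
  cc <- cell_centres(grid)
  xs <- rep(cc$x, each = grid$n_rows)
  ys <- rep(cc$y, times = grid$n_cols)
  matrix(on_water(habitat, xs, ys), grid$n_rows, grid$n_cols)
}
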