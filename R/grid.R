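#' Planar analysis grid
#'
#' A regular grid in planar metres with cell-centre registration: the centre of
#' cell (row i, col j) (0-based) is `origin + (index + 0.5) * cell_size`.
#' Rows index y (northing), columns index x (easting).
#'
#' @param origin_x,origin_y lower-left corner of the grid (m).
#' @param cell_size cell edge length (m), > 0.
#' @param n_rows,n_cols grid dimensions, >= 1.
#' @param crs_note free-text note on the projection in use.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs_note = "planar metres") {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs_note = crs_note),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with vectors `x` (length n_cols) and `y` (length n_rows).
#' @export
cell_centres <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Gridded probability surface (utilization distribution)
#'
#' Per-cell probability mass over a [grid_spec()]; the mass must sum to 1
#' (within 1e-9) unless the surface has been clipped to water, in which case
#' the remaining mass may be less than 1 and `clipped` is TRUE.
#'
#' @param grid a [grid_spec()].
#' @param density matrix (n_rows x n_cols) of non-negative cell masses.
#' @param water_mask logical matrix of the same shape (TRUE = water), or NULL.
#' @param clipped has land mass been removed (without renormalization)?
#' @return an object of class `probability_surface`.
#' @export
probability_surface <- function(grid, density, water_mask = NULL,
                                clipped = FALSE) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(density),
            nrow(density) == grid$n_rows, ncol(density) == grid$n_cols)
  if (any(density < 0)) stop("probability surface has negative mass")
  if (!clipped && abs(sum(density) - 1) > 1e-9) {
    stop("probability surface is not normalized (total mass ",
         format(sum(density)), ")")
  }
  if (!is.null(water_mask)) {
    stopifnot(is.logical(water_mask), all(dim(water_mask) == dim(density)))
    if (clipped && any(density[!water_mask] != 0)) {
      stop("clipped surface retains mass on land cells")
    }
  }
  structure(list(grid = grid, density = density, water_mask = water_mask,
                 clipped = clipped),
            class = "probability_surface")
}

#' @export
print.probability_surface <- function(x, ...) {
  cat(sprintf("probability_surface: %d x %d cells of %g m, total mass %.6f%s\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(x$density), if (x$clipped) " (land-clipped)" else ""))
  invisible(x)
}

#' @export
plot.probability_surface <- function(x, ...) {
  cc <- cell_centres(x$grid)
  graphics::image(cc$x, cc$y, t(x$density), xlab = "easting (m)",
                  ylab = "northing (m)", useRaster = TRUE, ...)
  invisible(x)
}

#' Highest-density contour region of a probability surface
#'
#' The smallest set of highest-density cells whose cumulative mass reaches
#' `level`; cells tied at the threshold density are all included, so the
#' result does not depend on iteration order.
#'
#' @param surface a [probability_surface()].
#' @param level fraction in (0, 1), e.g. 0.95.
#' @return an object of class `region_set`: the contour level, the (row, col)
#'   cell indices, cell-centre coordinates, and the region area in km^2
#'   (`|cells| * cell_size^2 / 1e6`).
#' @export
contour_region <- function(surface, level) {
  stopifnot(inherits(surface, "probability_surface"),
            level > 0, level < 1)
  total <- sum(surface$density)
  if (abs(total - 1) > 1e-9) {
    stop("contour_region needs a normalized surface (total mass ",
         format(total), "); renormalize or use an unclipped surface")
  }
  d <- as.vector(surface$density)
  ord <- order(d, decreasing = TRUE)
  cs <- cumsum(d[ord])
  k <- which(cs >= level - 1e-12)[1]
  thr <- d[ord[k]]
  keep <- which(d >= thr & d > 0)
  rows <- ((keep - 1) %% surface$grid$n_rows) + 1
  cols <- ((keep - 1) %/% surface$grid$n_rows) + 1
  region_set(level, rows, cols, surface$grid)
}

#' Construct a region (set of grid cells) at a contour level
#'
#' @param level contour level in (0,1).
#' @param rows,cols 1-based cell indices.
#' @param grid the underlying [grid_spec()].
#' @return object of class `region_set`.
#' @export
region_set <- function(level, rows, cols, grid) {
  cc <- cell_centres(grid)
  structure(list(level = level,
                 rows = as.integer(rows), cols = as.integer(cols),
                 x = cc$x[cols], y = cc$y[rows],
                 cell_size = grid$cell_size,
                 area_km2 = length(rows) * grid$cell_size^2 / 1e6),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %g%% contour, %d cells, %.4f km^2\n",
              100 * x$level, length(x$rows), x$area_km2))
  invisible(x)
}

#' Remove land cells from a region without renormalizing
#'
#' @param region a [region_set()].
#' @param water_mask logical matrix aligned to the region's grid.
#' @return a `region_set` restricted to water cells; `area_km2` shrinks
#'   accordingly.
#' @export
clip_region_to_water <- function(region, water_mask) {
  keep <- water_mask[cbind(region$rows, region$cols)]
  out <- region
  out$rows <- region$rows[keep]; out$cols <- region$cols[keep]
  out$x <- region$x[keep]; out$y <- region$y[keep]
  out$area_km2 <- sum(keep) * region$cell_size^2 / 1e6
  out
}

#' Zero out land mass on a surface (no renormalization)
#'
#' @param surface a [probability_surface()].
#' @param water_mask logical matrix (TRUE = water).
#' @param renormalize rescale remaining mass to 1?
#' @return a clipped `probability_surface`.
#' @export
clip_surface_to_water <- function(surface, water_mask, renormalize = FALSE) {
  d <- surface$density
  d[!water_mask] <- 0
  if (renormalize) {
    s <- sum(d)
    if (s <= 0) stop("no mass remains on water")
    d <- d / s
  }
  probability_surface(surface$grid, d, water_mask,
                      clipped = !renormalize)
}

#' Mass-conserving resampling of a surface onto another grid
#'
#' Each source cell's mass is distributed over target cells in proportion to
#' axis-aligned area overlap. Mass falling outside the target grid is lost, so
#' choose a covering target grid when comparing surfaces.
#'
#' @param surface a [probability_surface()].
#' @param target a [grid_spec()].
#' @return a `probability_surface` on `target` (not renormalized; flagged
#'   clipped if mass was lost).
#' @export
resample_surface <- function(surface, target) {
  Rr <- overlap_matrix(surface$grid$origin_y, surface$grid$cell_size,
                       surface$grid$n_rows,
                       target$origin_y, target$cell_size, target$n_rows)
  Rc <- overlap_matrix(surface$grid$origin_x, surface$grid$cell_size,
                       surface$grid$n_cols,
                       target$origin_x, target$cell_size, target$n_cols)
  d <- Rr %*% surface$density %*% t(Rc)
  lost <- abs(sum(d) - sum(surface$density)) > 1e-9
  probability_surface(target, d, clipped = lost || surface$clipped)
}

# Fraction-of-overlap matrix between two 1-D cell partitions:
# entry [t, s] = fraction of source cell s covered by target cell t.
overlap_matrix <- function(o_src, h_src, n_src, o_tgt, h_tgt, n_tgt) {
  s_lo <- o_src + (seq_len(n_src) - 1) * h_src
  t_lo <- o_tgt + (seq_len(n_tgt) - 1) * h_tgt
  lo <- outer(t_lo, s_lo, function(t, s) pmax(t, s))
  hi <- outer(t_lo + h_tgt, s_lo + h_src, function(t, s) pmin(t, s))
  pmax(hi - lo, 0) / h_src
}
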