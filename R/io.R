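#' Write a grid of values as ESRI ASCII raster
#'
#' Plain-text raster interchange for probability surfaces and habitat grids.
#' A `.prj.txt` sidecar records the CRS note.
#'
#' @param values numeric matrix (rows = y from south, cols = x from west).
#' @param grid a [grid_spec()].
#' @param path output file path (conventionally `.asc`).
#' @param nodata value to stand for missing cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin_x),
    sprintf("yllcorner %.6f", grid$origin_y),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  # ESRI ASCII rows run north to south
  for (i in rev(seq_len(grid$n_rows))) {
    writeLines(paste(format(vals[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  writeLines(grid$crs_note, paste0(path, ".prj.txt"))
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_ascii_grid()]
#'
#' @param path file path.
#' @return list with `grid` ([grid_spec()]) and `values` matrix.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  get <- function(i) as.numeric(kv[[i]][2])
  n_cols <- get(1); n_rows <- get(2)
  crs_note <- if (file.exists(paste0(path, ".prj.txt"))) {
    readLines(paste0(path, ".prj.txt"))[1]
  } else "planar metres"
  g <- grid_spec(get(3), get(4), get(5), n_rows, n_cols, crs_note)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == get(6)] <- NA
  list(grid = g, values = m[rev(seq_len(n_rows)), , drop = FALSE])
}

#' Serialize regions/coverages/polygons as GeoJSON
#'
#' Writes a FeatureCollection in the planar frame (coordinates in metres;
#' the CRS note goes into the collection properties).
#'
#' @param geoms named list of `mcp_polygon`, `disk_coverage`, or `region_set`
#'   objects.
#' @param path output path.
#' @param crs_note projection note stored with the collection.
#' @export
write_geojson <- function(geoms, path, crs_note = "planar metres") {
  feat <- lapply(names(geoms), function(nm) {
    g <- geoms[[nm]]
    geometry <- if (inherits(g, "mcp_polygon")) {
      ring <- cbind(c(g$x, g$x[1]), c(g$y, g$y[1]))
      list(type = "Polygon", coordinates = list(apply(ring, 1, as.list)))
    } else if (inherits(g, "disk_coverage")) {
      th <- seq(0, 2 * pi, length.out = 65)[-65]
      polys <- lapply(seq_along(g$x), function(i) {
        ring <- cbind(g$x[i] + g$radii[i] * cos(th),
                      g$y[i] + g$radii[i] * sin(th))
        ring <- rbind(ring, ring[1, ])
        list(apply(ring, 1, as.list))
      })
      list(type = "MultiPolygon", coordinates = polys)
    } else if (inherits(g, "region_set")) {
      h <- g$cell_size / 2
      polys <- lapply(seq_along(g$x), function(i) {
        ring <- cbind(g$x[i] + c(-h, h, h, -h, -h),
                      g$y[i] + c(-h, -h, h, h, -h))
        list(apply(ring, 1, as.list))
      })
      list(type = "MultiPolygon", coordinates = polys)
    } else stop("unsupported geometry class: ", class(g)[1])
    list(type = "Feature", properties = list(name = nm), geometry = geometry)
  })
  obj <- list(type = "FeatureCollection",
              properties = list(crs_note = crs_note),
              features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

# ISO-8601 UTC timestamp helpers used by all CSV schemas
format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_utc <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
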