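#' Rectified analysis grid
#'
#' An `analysis_grid` describes the regular, axis-aligned raster grid onto
#' which every layer of a case study is rectified: a rectangular extent in a
#' projected coordinate reference system (linear units of meters), a square
#' cell size, and a boolean per-cell membership mask delimiting the area of
#' analysis. The pixel convention is origin at the top-left corner, row-major
#' storage, pixel-is-area, with half-open cell intervals `[x, x + res)` in
#' easting and `(y - res, y]` in northing.
#'
#' @param extent numeric of length 4, `c(xmin, ymin, xmax, ymax)` in meters.
#' @param resolution cell edge length in meters, `> 0`.
#' @param crs projected coordinate reference identifier (e.g. `"EPSG:3035"`).
#'   Geographic (degree-unit) systems are rejected.
#' @param area_polygon optional polygon (see [read_geojson()] for the feature
#'   format, or a list with `type`/`coordinates` in GeoJSON structure)
#'   delimiting the area of analysis; cells whose centers fall inside it form
#'   the area mask. When omitted the whole extent is in-area.
#'
#' @return an object of class `analysis_grid` with fields `extent`,
#'   `resolution`, `crs`, `nrow`, `ncol` and logical matrix `area_mask`.
#' @examples
#' g <- make_grid(c(0, 0, 10000, 10000), 500, "EPSG:3035")
#' dim(g$area_mask)  # 20 x 20
#' @export
make_grid <- function(extent, resolution, crs, area_polygon = NULL) {
  extent <- as.numeric(extent)
  if (length(extent) != 4L || anyNA(extent))
    stop("extent must be numeric c(xmin, ymin, xmax, ymax)")
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent is degenerate: xmax must exceed xmin and ymax must exceed ymin")
  if (!is.numeric(resolution) || length(resolution) != 1L || is.na(resolution) ||
      resolution <= 0)
    stop("resolution must be a single positive number (meters)")
  if (is_geographic_crs(crs))
    stop("crs '", crs, "' uses geographic (degree) units; a projected ",
         "meter-unit crs is required")
  ncol <- as.integer(ceiling((extent[3] - extent[1]) / resolution))
  nrow <- as.integer(ceiling((extent[4] - extent[2]) / resolution))
  g <- structure(
    list(extent = extent, resolution = as.numeric(resolution),
         crs = as.character(crs), nrow = nrow, ncol = ncol,
         area_mask = matrix(TRUE, nrow, ncol)),
    class = "analysis_grid")
  if (!is.null(area_polygon)) {
    cc <- cell_centers(g)
    inside <- points_in_polygon(cc$x, cc$y, area_polygon)
    g$area_mask <- matrix(inside, nrow, ncol, byrow = TRUE)
    if (!any(g$area_mask)) stop("area_polygon covers no grid cell center")
  }
  g
}

# Heuristic guard: no geodesy engine is bundled, so the crs is carried as an
# opaque identifier and only screened against well-known geographic systems.
is_geographic_crs <- function(crs) {
  crs <- tolower(as.character(crs))
  geo_codes <- c("4326", "4258", "4269", "4267", "4979", "4937", "4759")
  code <- sub("^.*:", "", crs)
  code %in% geo_codes || grepl("longlat|latlong|degree", crs)
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("analysis_grid: %d x %d cells @ %g m [%s]\n",
              x$nrow, x$ncol, x$resolution, x$crs))
  cat(sprintf("  extent: [%g, %g] x [%g, %g] m\n",
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  cat(sprintf("  in-area cells: %d / %d\n", sum(x$area_mask),
              x$nrow * x$ncol))
  invisible(x)
}

# Cell-center coordinates in row-major order (row 1 = top row).
cell_centers <- function(grid) {
  xs <- grid$extent[1] + (seq_len(grid$ncol) - 0.5) * grid$resolution
  ys <- grid$extent[4] - (seq_len(grid$nrow) - 0.5) * grid$resolution
  list(x = rep(xs, times = grid$nrow),
       y = rep(ys, each = grid$ncol))
}

# Geometry equality (extent/resolution/crs/shape); the area mask is not part
# of alignment, so a subset case study can reuse layers unchanged.
same_geometry <- function(a, b) {
  isTRUE(all.equal(a$extent, b$extent)) &&
    isTRUE(all.equal(a$resolution, b$resolution)) &&
    identical(a$crs, b$crs) && a$nrow == b$nrow && a$ncol == b$ncol
}

stopifnot_aligned <- function(layer, grid) {
  if (!same_geometry(layer$grid, grid))
    stop("layer '", layer$name, "' is not aligned to the analysis grid ",
         "(extent/resolution/crs mismatch)")
  invisible(TRUE)
}

#' Georeferenced grid layer
#'
#' A `grid_layer` is a named 2D array of intensities aligned to an
#' [make_grid()] analysis grid. Nodata cells are stored as `NA`; all other
#' values must be finite. Layers are the common currency of the package:
#' human-use footprints, environmental components and pressure fields are all
#' grid layers.
#'
#' @param name layer identifier.
#' @param values numeric matrix of dimension `grid$nrow x grid$ncol`; `NA`
#'   marks nodata.
#' @param grid the [make_grid()] grid the values are aligned to.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(name, values, grid) {
  if (!inherits(grid, "analysis_grid")) stop("grid must be an analysis_grid")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol)
    stop("values shape ", nrow(values), "x", ncol(values),
         " does not match grid shape ", grid$nrow, "x", grid$ncol)
  if (any(is.infinite(values)))
    stop("layer '", name, "' contains non-finite values")
  structure(list(name = as.character(name), values = values, grid = grid),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("grid_layer '%s': %d x %d cells, %d nodata\n", x$name,
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  invisible(x)
}

# Constant layer on a grid (used by the expression evaluator).
constant_layer <- function(value, grid, name = "const") {
  grid_layer(name, matrix(value, grid$nrow, grid$ncol), grid)
}

#' Rasterize vector features onto an analysis grid
#'
#' Burns a feature collection (polygons, lines or points) onto the grid. A
#' cell is covered by a polygon when its center falls inside the polygon
#' (even-odd rule; deterministic and resolution-consistent); lines and points
#' burn every cell they touch. In `"presence"` mode the result is binary
#' (cell covered by at least one feature); in `"burn_value"` mode each
#' feature contributes the value of its `value_field` property and
#' overlapping features accumulate by summation, so disjoint feature sets are
#' additive.
#'
#' @param features a feature collection from [read_geojson()], or a bare list
#'   of features (each a list with `geometry` and `properties`).
#' @param grid target [make_grid()] grid.
#' @param value_field property name supplying burn values (required in
#'   `"burn_value"` mode).
#' @param mode `"presence"` (binary output) or `"burn_value"`.
#' @param name name for the output layer.
#' @return a [grid_layer()] aligned to `grid`.
#' @export
rasterize_features <- function(features, grid, value_field = NULL,
                               mode = c("presence", "burn_value"),
                               name = "rasterized") {
  mode <- match.arg(mode)
  feats <- as_feature_list(features, grid)
  out <- matrix(0, grid$nrow, grid$ncol)
  if (mode == "burn_value" && is.null(value_field))
    stop("value_field is required in burn_value mode")
  for (f in feats) {
    covered <- feature_coverage(f$geometry, grid)
    if (mode == "presence") {
      out[covered] <- 1
    } else {
      v <- f$properties[[value_field]]
      if (is.null(v) || !is.numeric(v))
        stop("feature lacks numeric value_field '", value_field, "'")
      out[covered] <- out[covered] + v
    }
  }
  grid_layer(name, out, grid)
}

# Normalize the accepted feature inputs to a plain list of features and check
# crs compatibility against the grid (no reprojection engine is bundled).
as_feature_list <- function(features, grid) {
  if (inherits(features, "msp_features")) {
    if (!is.null(features$crs) && !identical(features$crs, grid$crs))
      stop("feature crs '", features$crs, "' does not match grid crs '",
           grid$crs, "' and no reprojection is available")
    return(features$features)
  }
  if (is.list(features)) {
    # bare geometry -> single anonymous feature
    if (!is.null(features$type) && !is.null(features$coordinates))
      return(list(list(geometry = features, properties = list())))
    return(features)
  }
  stop("unsupported features object")
}

# Logical coverage matrix of one geometry.
feature_coverage <- function(geom, grid) {
  type <- geom$type
  if (is.null(type)) stop("geometry lacks a type")
  if (type %in% c("Polygon", "MultiPolygon")) {
    cc <- cell_centers(grid)
    inside <- points_in_polygon(cc$x, cc$y, geom)
    matrix(inside, grid$nrow, grid$ncol, byrow = TRUE)
  } else if (type %in% c("LineString", "MultiLineString")) {
    lines <- if (type == "LineString") list(geom$coordinates) else
      geom$coordinates
    cov <- matrix(FALSE, grid$nrow, grid$ncol)
    for (ln in lines) {
      xy <- coord_matrix(ln)
      cov <- cov | line_coverage(xy, grid)
    }
    cov
  } else if (type %in% c("Point", "MultiPoint")) {
    pts <- if (type == "Point") matrix(unlist(geom$coordinates[1:2]),
                                       ncol = 2) else coord_matrix(geom$coordinates)
    cov <- matrix(FALSE, grid$nrow, grid$ncol)
    idx <- cell_index(pts[, 1], pts[, 2], grid)
    cov[idx[!is.na(idx)]] <- TRUE
    cov
  } else stop("unsupported geometry type '", type, "'")
}

# GeoJSON coordinate arrays arrive either as numeric matrices (jsonlite
# simplification) or as nested lists; coerce to an n x 2 matrix.
coord_matrix <- function(coords) {
  if (is.matrix(coords)) return(coords[, 1:2, drop = FALSE])
  do.call(rbind, lapply(coords, function(p) as.numeric(p)[1:2]))
}

# Linear cell index (column-major into the values matrix) of points; NA when
# outside the extent. Half-open convention: a point on the right/top edge of
# the extent is outside.
cell_index <- function(x, y, grid) {
  col <- floor((x - grid$extent[1]) / grid$resolution) + 1
  row <- floor((grid$extent[4] - y) / grid$resolution) + 1
  # points exactly on the top edge belong to row 1 (half-open (y-res, y])
  row[y == grid$extent[4]] <- 1
  ok <- col >= 1 & col <= grid$ncol & row >= 1 & row <= grid$nrow
  idx <- rep(NA_integer_, length(x))
  idx[ok] <- (col[ok] - 1L) * grid$nrow + row[ok]
  idx
}

# Cells touched by a polyline: sample each segment densely relative to the
# cell size (step = res / 5), plus the vertices themselves.
line_coverage <- function(xy, grid) {
  cov <- matrix(FALSE, grid$nrow, grid$ncol)
  if (nrow(xy) == 0) return(cov)
  pts_x <- xy[1, 1]; pts_y <- xy[1, 2]
  if (nrow(xy) > 1) {
    for (i in seq_len(nrow(xy) - 1)) {
      len <- sqrt(sum((xy[i + 1, ] - xy[i, ])^2))
      n <- max(2L, ceiling(len / (grid$resolution / 5)) + 1L)
      t <- seq(0, 1, length.out = n)
      pts_x <- c(pts_x, xy[i, 1] + t * (xy[i + 1, 1] - xy[i, 1]))
      pts_y <- c(pts_y, xy[i, 2] + t * (xy[i + 1, 2] - xy[i, 2]))
    }
  }
  idx <- cell_index(pts_x, pts_y, grid)
  cov[unique(idx[!is.na(idx)])] <- TRUE
  cov
}

# Point-in-polygon for Polygon / MultiPolygon geometries using the even-odd
# rule: a point is inside when it lies within an odd number of rings (outer
# boundaries and holes alike). Delegates to mgcv::in.out with NA-separated
# loops.
points_in_polygon <- function(x, y, geom) {
  rings <- polygon_rings(geom)
  if (!length(rings)) return(rep(FALSE, length(x)))
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(x, y))
}

polygon_rings <- function(geom) {
  if (!is.null(geom$geometry)) geom <- geom$geometry
  type <- geom$type
  if (is.null(type)) stop("polygon geometry lacks a type")
  polys <- switch(type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    stop("expected Polygon or MultiPolygon, got '", type, "'"))
  rings <- list()
  for (poly in polys)
    for (ring in poly)
      rings[[length(rings) + 1L]] <- coord_matrix(ring)
  rings
}
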