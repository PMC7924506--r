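NODATA_SENTINEL <- -9999

#' Write a grid layer as an ESRI ASCII grid
#'
#' Serializes a layer to the plain-text `.asc` raster format (six header
#' lines followed by rows of values, top row first). Nodata cells are written
#' as the sentinel `-9999`; values are written with 17 significant digits so
#' a write/read round trip is bit-exact. The crs is not part of the `.asc`
#' format and travels in the case-study manifest or report metadata.
#'
#' @param layer a [grid_layer()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  g <- layer$grid
  v <- layer$values
  v[is.na(v)] <- NODATA_SENTINEL
  header <- c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.17g", g$extent[1]),
    sprintf("yllcorner %.17g", g$extent[2]),
    sprintf("cellsize %.17g", g$resolution),
    sprintf("NODATA_value %d", NODATA_SENTINEL))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Parses a `.asc` raster. When `grid` is supplied the file geometry must
#' match it exactly (this is how case-study loading enforces alignment);
#' otherwise a grid is built from the file header with `crs`.
#'
#' @param path file path.
#' @param grid optional [make_grid()] grid the raster must align to.
#' @param crs crs identifier to stamp on the grid when `grid` is not given.
#' @param name layer name (defaults to the file base name).
#' @return a [grid_layer()].
#' @export
read_ascii_grid <- function(path, grid = NULL, crs = "EPSG:3035",
                            name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, " holds ", length(vals), " values, expected ",
         nr * nc)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  file_extent <- c(hdr$xllcorner, hdr$yllcorner,
                   hdr$xllcorner + nc * hdr$cellsize,
                   hdr$yllcorner + nr * hdr$cellsize)
  if (is.null(grid)) {
    grid <- make_grid(file_extent, hdr$cellsize, crs)
  } else {
    ok <- isTRUE(all.equal(file_extent, grid$extent)) &&
      isTRUE(all.equal(hdr$cellsize, grid$resolution)) &&
      nr == grid$nrow && nc == grid$ncol
    if (!ok)
      stop("raster ", path, " is not aligned to the analysis grid")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid_layer(name, m, grid)
}

#' Read a GeoJSON feature collection
#'
#' Parses a GeoJSON file into a lightweight feature collection: a list with
#' a `crs` identifier and a list of features, each holding `geometry` and
#' `properties`. Bare `Feature` and bare geometry documents are promoted to
#' collections. GeoJSON's default crs is geographic, so files used with an
#' analysis grid should carry a named projected crs member; absent that, the
#' collection's crs is `NULL` and no crs check is possible.
#'
#' @param path GeoJSON file path.
#' @return an object of class `msp_features`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  crs <- NULL
  if (!is.null(doc$crs$properties$name)) crs <- doc$crs$properties$name
  feats <- switch(
    doc$type %||% "",
    FeatureCollection = doc$features,
    Feature = list(doc),
    Polygon = , MultiPolygon = , LineString = , MultiLineString = ,
    Point = , MultiPoint =
      list(list(geometry = doc, properties = list())),
    stop("unsupported GeoJSON document type in ", path))
  feats <- lapply(feats, function(f) {
    if (is.null(f$geometry)) stop("feature without geometry in ", path)
    list(geometry = f$geometry, properties = f$properties %||% list())
  })
  structure(list(crs = crs, features = feats), class = "msp_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a grid definition as JSON
#'
#' The grid definition (`extent`, `resolution`, `crs`, optional
#' `area_polygon`) is the JSON object embedded in a case-study manifest.
#'
#' @param grid an [make_grid()] grid.
#' @param area_polygon optional polygon to embed (the mask itself is always
#'   reproducible from it).
#' @return `grid_to_json`: a list ready for JSON serialization;
#'   `grid_from_json`: an `analysis_grid`.
#' @export
grid_to_json <- function(grid, area_polygon = NULL) {
  out <- list(extent = grid$extent, resolution = grid$resolution,
              crs = grid$crs)
  if (!is.null(area_polygon)) out$area_polygon <- area_polygon
  out
}

#' @rdname grid_to_json
#' @param obj a list parsed from the manifest JSON.
#' @export
grid_from_json <- function(obj) {
  make_grid(unlist(obj$extent), obj$resolution, obj$crs,
            area_polygon = obj$area_polygon)
}
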