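#' Statistics of a grid layer
#'
#' Summary statistics over the in-area, non-nodata cells of a layer: count,
#' mean, standard deviation, extremes, the 5/25/50/75/95 percentiles
#' (computed by linear interpolation between order statistics, quantile
#' type 7) and a histogram whose bin edges span `[min, max]` exactly. A
#' constant layer yields a single-bin histogram. Histogram counts always sum
#' to the cell count.
#'
#' @param layer a [grid_layer()] with at least one in-area, non-nodata cell.
#' @param n_bins number of histogram bins (default 50).
#' @return an object of class `layer_stats`: `n_cells`, `mean`, `std`,
#'   `min`, `max`, `percentiles`, `histogram` (list of `edges`, `counts`).
#' @export
layer_statistics <- function(layer, n_bins = 50) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  v <- layer$values[layer$grid$area_mask]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("layer '", layer$name, "' has no in-area, non-nodata cell")
  qs <- stats::quantile(v, c(.05, .25, .50, .75, .95), names = FALSE,
                        type = 7)
  mn <- min(v); mx <- max(v)
  if (mx == mn) {
    edges <- c(mn, mx)
    counts <- length(v)
  } else {
    edges <- seq(mn, mx, length.out = n_bins + 1L)
    idx <- pmin(findInterval(v, edges), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(
    n_cells = length(v), mean = mean(v),
    std = if (length(v) > 1L) stats::sd(v) else 0,
    min = mn, max = mx,
    percentiles = stats::setNames(qs, c("p5", "p25", "p50", "p75", "p95")),
    histogram = list(edges = edges, counts = as.integer(counts))),
    class = "layer_stats")
}

#' @export
print.layer_stats <- function(x, ...) {
  cat(sprintf("layer_stats: n=%d mean=%g sd=%g range=[%g, %g]\n",
              x$n_cells, x$mean, x$std, x$min, x$max))
  cat("  percentiles:",
      paste(names(x$percentiles), signif(x$percentiles, 6), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Write a model result to disk
#'
#' Writes a [muc_map()] or [cea_map()] result as a report directory: score
#' rasters in the plain-text ESRI ASCII grid format, contribution tables as
#' UTF-8 CSV, layer statistics and run metadata as JSON. Data files carry no
#' timestamps (only `run.json` does), so re-running on identical input
#' reproduces identical tables and raster values.
#'
#' For a CEA result the directory holds `cea.asc`, one
#' `cea_partials/<pressure>__<env>.asc` per sensitivity entry,
#' `pressures/<pressure>.asc`, and `cea_contributions.csv`; for a MUC result
#' `muc.asc` and `muc_pairs.csv`.
#'
#' @param result a `muc_result` or `cea_result`.
#' @param out_dir output directory (created if absent).
#' @return character vector of the files written (the manifest), invisibly
#'   also saved as `manifest.json`.
#' @export
write_report <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  files <- character()
  add <- function(p) files <<- c(files, p)
  if (inherits(result, "muc_result")) {
    p <- file.path(out_dir, "muc.asc")
    write_ascii_grid(result$score_map, p); add(p)
    p <- file.path(out_dir, "muc_pairs.csv")
    utils::write.csv(result$pair_contributions, p, row.names = FALSE); add(p)
    stats <- list(muc = unclass(layer_statistics(result$score_map)))
    model <- "muc"
  } else if (inherits(result, "cea_result")) {
    p <- file.path(out_dir, "cea.asc")
    write_ascii_grid(result$total_map, p); add(p)
    pdir <- file.path(out_dir, "cea_partials")
    dir.create(pdir, showWarnings = FALSE)
    for (k in names(result$partials)) {
      p <- file.path(pdir, paste0(k, ".asc"))
      write_ascii_grid(result$partials[[k]], p); add(p)
    }
    prdir <- file.path(out_dir, "pressures")
    dir.create(prdir, showWarnings = FALSE)
    for (k in names(result$pressure_maps)) {
      p <- file.path(prdir, paste0(k, ".asc"))
      write_ascii_grid(result$pressure_maps[[k]], p); add(p)
    }
    p <- file.path(out_dir, "cea_contributions.csv")
    utils::write.csv(partial_effects(result, "pair"), p, row.names = FALSE)
    add(p)
    stats <- list(cea = unclass(layer_statistics(result$total_map)))
    model <- "cea"
  } else stop("result must be a muc_result or cea_result")
  p <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(p)
  meta <- list(model = model,
               provenance = result$provenance %||% list(),
               crs = layer_of(result)$grid$crs,
               written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  p <- file.path(out_dir, "run.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE)
  add(p)
  rel <- substring(files, nchar(out_dir) + 2L)  # paths relative to out_dir
  jsonlite::write_json(rel, file.path(out_dir, "manifest.json"))
  files
}

layer_of <- function(result)
  if (inherits(result, "muc_result")) result$score_map else result$total_map
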