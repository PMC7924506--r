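#' Assemble a case study in memory
#'
#' A case study bundles everything one CEA or MUC run needs: the analysis
#' grid, registries of use / environmental / pressure layers, the COEXIST
#' use attributes, the use-to-pressure links (weights and propagation
#' distances) and the pressure-by-receptor sensitivities. Environmental
#' layers are normalized to unit maximum on construction. Structural
#' problems (misaligned layers, dangling identifiers) are errors; see
#' [validate_case_study()] for the full report including model-specific
#' requirements.
#'
#' @param grid an [make_grid()] analysis grid.
#' @param uses,envs,pressure_layers named lists of aligned [grid_layer()]s
#'   (`pressure_layers` holds directly supplied pressure fields and may be
#'   empty: pressures are usually derived from uses via `links`).
#' @param use_attributes named list of [use_attributes()].
#' @param links data frame `use, pressure, weight, distance_m` (may be
#'   empty for MUC-only studies).
#' @param sensitivities data frame `pressure, env, sensitivity` (may be
#'   empty for MUC-only studies).
#' @param pressures character vector of pressure identifiers; defaults to
#'   those appearing in `links` and `pressure_layers`.
#' @param title,version metadata strings.
#' @return an object of class `case_study`.
#' @export
case_study <- function(grid, uses = list(), envs = list(),
                       pressure_layers = list(),
                       use_attributes = list(),
                       links = empty_links(), sensitivities = empty_sens(),
                       pressures = NULL, title = "untitled",
                       version = "1") {
  if (!inherits(grid, "analysis_grid")) stop("grid must be an analysis_grid")
  links <- if (nrow(as.data.frame(links))) validate_links(links) else
    empty_links()
  sensitivities <- if (nrow(as.data.frame(sensitivities)))
    validate_sensitivities(sensitivities) else empty_sens()
  envs <- lapply(envs, normalize_layer)
  if (is.null(pressures))
    pressures <- unique(c(links$pressure, names(pressure_layers)))
  cs <- structure(list(
    grid = grid, uses = uses, envs = envs,
    pressure_layers = pressure_layers,
    pressures = unique(as.character(pressures)),
    use_attributes = use_attributes,
    links = links, sensitivities = sensitivities,
    title = as.character(title), version = as.character(version)),
    class = "case_study")
  rep <- validate_case_study(cs)
  structural <- rep$errors[!grepl("^\\[(cea|muc)\\]", rep$errors)]
  if (length(structural))
    stop("invalid case study:\n  ", paste(structural, collapse = "\n  "))
  cs
}

empty_links <- function()
  data.frame(use = character(), pressure = character(), weight = numeric(),
             distance_m = numeric(), stringsAsFactors = FALSE)

empty_sens <- function()
  data.frame(pressure = character(), env = character(),
             sensitivity = numeric(), stringsAsFactors = FALSE)

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("case_study '%s' (v%s)\n", x$title, x$version))
  print(x$grid)
  cat(sprintf("  uses: %d, envs: %d, pressures: %d (%d direct layer(s))\n",
              length(x$uses), length(x$envs), length(x$pressures),
              length(x$pressure_layers)))
  cat(sprintf("  links: %d, sensitivities: %d\n", nrow(x$links),
              nrow(x$sensitivities)))
  invisible(x)
}

#' Validate a case study
#'
#' Checks every invariant and reports problems instead of throwing:
#' alignment of all layers, dangling identifiers in links and
#' sensitivities, value ranges (weights outside `[0, 1]` are warnings;
#' negative distances or sensitivities are errors) and model-specific
#' requirements, reported with a `[muc]` / `[cea]` prefix (missing use
#' attributes for MUC; missing links or sensitivities for CEA).
#'
#' @param cs a [case_study()].
#' @return an object of class `validation_report`: character vectors
#'   `errors` and `warnings`.
#' @export
validate_case_study <- function(cs) {
  errors <- character(); warnings <- character()
  err <- function(...) errors <<- c(errors, paste0(...))
  wrn <- function(...) warnings <<- c(warnings, paste0(...))
  all_layers <- c(cs$uses, cs$envs, cs$pressure_layers)
  for (nm in names(all_layers)) {
    l <- all_layers[[nm]]
    if (!inherits(l, "grid_layer")) { err("'", nm, "' is not a grid_layer"); next }
    if (!same_geometry(l$grid, cs$grid))
      err("layer '", nm, "' is not aligned to the case-study grid")
  }
  for (nm in names(cs$envs)) {
    v <- cs$envs[[nm]]$values
    if (any(v < 0 | v > 1 + 1e-9, na.rm = TRUE))
      err("environmental layer '", nm, "' is not normalized to [0, 1]")
  }
  if (nrow(cs$links)) {
    bad <- setdiff(cs$links$use, names(cs$uses))
    for (b in bad) err("pressure link references unknown use '", b, "'")
    bad <- setdiff(cs$links$pressure, cs$pressures)
    for (b in bad) err("pressure link references unknown pressure '", b, "'")
    out <- cs$links$weight < 0 | cs$links$weight > 1
    if (any(out))
      wrn("pressure weight(s) outside [0, 1]: ",
          paste(signif(cs$links$weight[out], 4), collapse = ", "))
    if (any(cs$links$distance_m < 0))
      err("negative propagation distance in pressure links")
  }
  if (nrow(cs$sensitivities)) {
    bad <- setdiff(cs$sensitivities$pressure, cs$pressures)
    for (b in bad) err("sensitivity references unknown pressure '", b, "'")
    bad <- setdiff(cs$sensitivities$env, names(cs$envs))
    for (b in bad)
      err("sensitivity references unknown environmental component '", b, "'")
    if (any(cs$sensitivities$sensitivity < 0))
      err("negative sensitivity")
  }
  for (nm in names(cs$use_attributes))
    if (!inherits(cs$use_attributes[[nm]], "use_attributes"))
      err("use_attributes entry '", nm, "' is not a use_attributes object")
  if (!any(cs$grid$area_mask)) err("area of analysis is empty")
  # model-specific requirements
  miss <- setdiff(names(cs$uses), names(cs$use_attributes))
  for (b in miss) err("[muc] use '", b, "' lacks COEXIST attributes")
  if (!length(cs$uses)) wrn("[muc] no use layers: MUC map will be all zero")
  if (!nrow(cs$sensitivities))
    err("[cea] sensitivities table is missing or empty: cannot run CEA")
  if (!nrow(cs$links) && !length(cs$pressure_layers))
    err("[cea] no pressure links and no direct pressure layers")
  if (!length(cs$envs)) err("[cea] no environmental component layers")
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

model_errors <- function(rep, model) {
  tag <- paste0("[", model, "]")
  c(rep$errors[!grepl("^\\[(cea|muc)\\]", rep$errors)],
    rep$errors[startsWith(rep$errors, tag)])
}

#' Load a case study from a directory
#'
#' Reads the documented bundle layout: a `casestudy.json` manifest (grid
#' definition, metadata, per-layer entries), a `layers/` directory of
#' rasters (`.asc`) and vectors (`.geojson`), and an `inputs/` directory of
#' `use_attributes.csv`, `pressure_links.csv` and `sensitivities.csv`.
#' Loading is two-stage, mirroring the layers-then-inputs workflow: all
#' layer files are read (vectors rasterized onto the grid), per-layer
#' pre-processing expressions are evaluated against the raw registry, then
#' the tabular inputs are read and the assembled study is validated.
#' Missing input tables load as empty (a MUC-only bundle need not ship
#' sensitivities); [run_cea()] refuses such a study with a named error.
#'
#' @param path case-study directory.
#' @return a [case_study()].
#' @export
load_case_study <- function(path) {
  manifest_path <- file.path(path, "casestudy.json")
  if (!file.exists(manifest_path))
    stop("missing manifest: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$grid)) stop("manifest lacks a grid definition")
  grid <- grid_from_json(man$grid)
  if (!is.null(man$grid$area_mask_file)) {
    mf <- file.path(path, man$grid$area_mask_file)
    if (!file.exists(mf)) stop("area mask raster not found: ", mf)
    mk <- read_ascii_grid(mf, grid = grid, name = "area_mask")
    grid$area_mask <- !is.na(mk$values) & mk$values != 0
    if (!any(grid$area_mask)) stop("area mask raster is empty")
  }
  raw <- list(); roles <- character()
  for (entry in man$layers %||% list()) {
    nm <- entry$name
    if (is.null(nm) || is.null(entry$role) || is.null(entry$file))
      stop("manifest layer entry needs name, role and file")
    if (!entry$role %in% c("use", "env", "pressure"))
      stop("layer '", nm, "' has unknown role '", entry$role, "'")
    f <- file.path(path, entry$file)
    if (!file.exists(f))
      stop("layer '", nm, "': referenced file not found: ", f)
    layer <- if (grepl("\\.asc$", f, ignore.case = TRUE)) {
      read_ascii_grid(f, grid = grid, name = nm)
    } else if (grepl("\\.(geojson|json)$", f, ignore.case = TRUE)) {
      feats <- read_geojson(f)
      if (is.null(feats$crs)) feats$crs <- grid$crs  # trust bundled vectors
      if (!is.null(entry$value_field))
        rasterize_features(feats, grid, value_field = entry$value_field,
                           mode = "burn_value", name = nm)
      else rasterize_features(feats, grid, mode = "presence", name = nm)
    } else stop("layer '", nm, "': unsupported file type: ", entry$file)
    raw[[nm]] <- layer
    roles[nm] <- entry$role
  }
  # second pass: pre-processing expressions see the full raw registry
  for (entry in man$layers %||% list()) {
    if (is.null(entry$expression)) next
    nm <- entry$name
    raw[[nm]] <- evaluate_expression(entry$expression, raw, grid = grid,
                                     name = nm)
  }
  inputs <- file.path(path, "inputs")
  attrs <- read_use_attributes(file.path(inputs, "use_attributes.csv"))
  links <- read_links_csv(file.path(inputs, "pressure_links.csv"))
  sens <- read_sens_csv(file.path(inputs, "sensitivities.csv"))
  case_study(
    grid = grid,
    uses = raw[roles[names(raw)] == "use"],
    envs = raw[roles[names(raw)] == "env"],
    pressure_layers = raw[roles[names(raw)] == "pressure"],
    use_attributes = attrs, links = links, sensitivities = sens,
    pressures = unlist(man$pressures),
    title = man$title %||% basename(path),
    version = man$version %||% "1")
}

read_use_attributes <- function(path) {
  if (!file.exists(path)) return(list())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("use", "vertical_domain", "spatial_domain", "temporal_domain",
            "mobility")
  if (!all(need %in% names(df)))
    stop("use_attributes.csv needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df)))
    out[[df$use[i]]] <- use_attributes(
      strsplit(df$vertical_domain[i], ";", fixed = TRUE)[[1L]],
      df$spatial_domain[i], df$temporal_domain[i], df$mobility[i])
  out
}

read_links_csv <- function(path) {
  if (!file.exists(path)) return(empty_links())
  validate_links(utils::read.csv(path, stringsAsFactors = FALSE))
}

read_sens_csv <- function(path) {
  if (!file.exists(path)) return(empty_sens())
  validate_sensitivities(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Save a case study to a directory
#'
#' Writes the bundle layout consumed by [load_case_study()]. Layers are
#' written as `.asc` rasters with full (17 significant digit) precision, so
#' a save/load round trip reproduces every value bit-exactly; the tabular
#' inputs round-trip exactly as CSV. Pre-processing expressions are not
#' saved: layers are persisted in their derived, model-ready form.
#'
#' @param cs a [case_study()].
#' @param path target directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return `path`, invisibly.
#' @export
save_case_study <- function(cs, path, overwrite = FALSE) {
  if (dir.exists(path) && length(dir(path)) && !overwrite)
    stop("directory ", path, " exists and is not empty; set overwrite = TRUE")
  dir.create(file.path(path, "layers"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "inputs"), showWarnings = FALSE)
  entries <- list()
  write_group <- function(layers, role) {
    for (nm in names(layers)) {
      rel <- file.path("layers", paste0(nm, ".asc"))
      write_ascii_grid(layers[[nm]], file.path(path, rel))
      entries[[length(entries) + 1L]] <<-
        list(name = nm, role = role, file = rel)
    }
  }
  write_group(cs$uses, "use")
  write_group(cs$envs, "env")
  write_group(cs$pressure_layers, "pressure")
  area_polygon <- NULL
  if (!all(cs$grid$area_mask)) {
    # persist the mask as a dedicated raster; reconstructed at load time
    mask_layer <- grid_layer("area_mask",
                             matrix(as.numeric(cs$grid$area_mask),
                                    cs$grid$nrow, cs$grid$ncol),
                             strip_mask(cs$grid))
    write_ascii_grid(mask_layer, file.path(path, "layers", "area_mask.asc"))
  }
  man <- list(title = cs$title, version = cs$version,
              grid = grid_to_json(cs$grid),
              pressures = as.list(cs$pressures),
              layers = entries)
  if (!all(cs$grid$area_mask)) man$grid$area_mask_file <- "layers/area_mask.asc"
  jsonlite::write_json(man, file.path(path, "casestudy.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(cs$use_attributes)) {
    df <- data.frame(
      use = names(cs$use_attributes),
      vertical_domain = vapply(cs$use_attributes, function(a)
        paste(a$vertical_domain, collapse = ";"), ""),
      spatial_domain = vapply(cs$use_attributes, `[[`, "", "spatial_domain"),
      temporal_domain = vapply(cs$use_attributes, `[[`, "",
                               "temporal_domain"),
      mobility = vapply(cs$use_attributes, `[[`, "", "mobility"),
      stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(path, "inputs", "use_attributes.csv"),
                     row.names = FALSE)
  }
  if (nrow(cs$links))
    utils::write.csv(cs$links, file.path(path, "inputs", "pressure_links.csv"),
                     row.names = FALSE)
  if (nrow(cs$sensitivities))
    utils::write.csv(cs$sensitivities,
                     file.path(path, "inputs", "sensitivities.csv"),
                     row.names = FALSE)
  invisible(path)
}

strip_mask <- function(grid) { grid$area_mask[] <- TRUE; grid }

#' Restrict a case study
#'
#' Restricts a case study to a subregion of analysis and/or a custom
#' combination of human uses, pressures and environmental components, the
#' way a webtool user configures a run. Links and sensitivities are
#' filtered consistently with the surviving registries. Selecting zero uses
#' is allowed (the MUC map of an empty selection is all zero); an empty
#' resulting area is an error.
#'
#' @param cs a [case_study()].
#' @param subregion optional polygon (feature collection, feature or bare
#'   geometry) intersected with the current area mask.
#' @param uses,envs,pressures optional character vectors naming the layers /
#'   pressures to keep; `NULL` keeps all.
#' @return a new [case_study()].
#' @export
subset_case_study <- function(cs, subregion = NULL, uses = NULL, envs = NULL,
                              pressures = NULL) {
  pick <- function(sel, have, what) {
    if (is.null(sel)) return(names(have))
    bad <- setdiff(sel, names(have))
    if (length(bad))
      stop("unknown ", what, ": ", paste(bad, collapse = ", "))
    sel
  }
  keep_u <- pick(uses, cs$uses, "use(s)")
  keep_e <- pick(envs, cs$envs, "environmental component(s)")
  keep_p <- if (is.null(pressures)) cs$pressures else {
    bad <- setdiff(pressures, cs$pressures)
    if (length(bad)) stop("unknown pressure(s): ", paste(bad, collapse = ", "))
    pressures
  }
  grid <- cs$grid
  if (!is.null(subregion)) {
    feats <- as_feature_list(subregion, grid)
    sub_mask <- matrix(FALSE, grid$nrow, grid$ncol)
    for (f in feats) sub_mask <- sub_mask | feature_coverage(f$geometry, grid)
    grid$area_mask <- grid$area_mask & sub_mask
    if (!any(grid$area_mask))
      stop("subregion does not intersect the area of analysis")
  }
  relayer <- function(layers)
    lapply(layers, function(l) grid_layer(l$name, l$values, grid))
  links <- cs$links[cs$links$use %in% keep_u &
                      cs$links$pressure %in% keep_p, , drop = FALSE]
  sens <- cs$sensitivities[cs$sensitivities$pressure %in% keep_p &
                             cs$sensitivities$env %in% keep_e, , drop = FALSE]
  cs2 <- structure(list(
    grid = grid,
    uses = relayer(cs$uses[keep_u]),
    envs = relayer(cs$envs[keep_e]),
    pressure_layers = relayer(
      cs$pressure_layers[intersect(names(cs$pressure_layers), keep_p)]),
    pressures = keep_p,
    use_attributes = cs$use_attributes[
      intersect(names(cs$use_attributes), keep_u)],
    links = links, sensitivities = sens,
    title = cs$title, version = cs$version), class = "case_study")
  cs2
}

#' Run the MUC model on a case study
#'
#' Thresholds the use layers into presence/absence, scores every use pair
#' from its COEXIST attributes and accumulates the per-cell conflict map.
#'
#' @param cs a [case_study()] with attributes for every use.
#' @param rules a [default_ruleset()].
#' @param threshold presence threshold passed to [presence_layers()].
#' @return a `muc_result` with provenance attached.
#' @export
run_muc <- function(cs, rules = default_ruleset(), threshold = 0) {
  rep <- validate_case_study(cs)
  errs <- model_errors(rep, "muc")
  if (length(errs))
    stop("case study is not runnable for MUC:\n  ",
         paste(errs, collapse = "\n  "))
  pres <- presence_layers(cs$uses, threshold = threshold)
  res <- if (length(pres))
    muc_map(pres, conflict_matrix(cs$use_attributes[names(cs$uses)], rules),
            cs$grid)
  else muc_map(list(), conflict_matrix_empty(), cs$grid)
  res$provenance <- run_provenance(cs, "muc")
  res
}

conflict_matrix_empty <- function()
  structure(matrix(numeric(), 0, 0), class = c("conflict_matrix", "matrix"))

#' Run the CEA model on a case study
#'
#' Assembles every pressure field (directly supplied pressure layers are
#' normalized and used as-is; the rest are propagated from the linked uses)
#' and combines them with the environmental components through the
#' sensitivity table.
#'
#' @param cs a [case_study()] with links/pressure layers and sensitivities.
#' @param normalize_pressures divide each pressure field by its maximum
#'   (default `TRUE`).
#' @return a `cea_result` with provenance attached.
#' @export
run_cea <- function(cs, normalize_pressures = TRUE) {
  rep <- validate_case_study(cs)
  errs <- model_errors(rep, "cea")
  if (length(errs))
    stop("case study is not runnable for CEA:\n  ",
         paste(errs, collapse = "\n  "))
  needed <- unique(cs$sensitivities$pressure)
  pmaps <- list()
  for (p in needed) {
    if (!is.null(cs$pressure_layers[[p]])) {
      pmaps[[p]] <- if (normalize_pressures)
        normalize_layer(cs$pressure_layers[[p]]) else cs$pressure_layers[[p]]
    } else if (p %in% cs$links$pressure) {
      pmaps[[p]] <- pressure_map(cs$uses, cs$links, p, cs$grid,
                                 normalize = normalize_pressures)
    } else {
      stop("pressure '", p, "' has neither a direct layer nor pressure links")
    }
  }
  res <- cea_map(pmaps, cs$envs, cs$sensitivities, cs$grid)
  res$provenance <- run_provenance(cs, "cea")
  res
}

run_provenance <- function(cs, model)
  list(case_study = cs$title, version = cs$version, model = model,
       n_uses = length(cs$uses), n_envs = length(cs$envs),
       n_pressures = length(cs$pressures),
       in_area_cells = sum(cs$grid$area_mask),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
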