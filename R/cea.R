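#' Pressure field from use layers
#'
#' Propagates and combines human-use layers into the field of one pressure
#' (e.g. underwater noise, abrasion, marine litter). Every use linked to the
#' pressure is smoothed with a Gaussian kernel of its propagation distance,
#' scaled by its relative pressure weight, and the weighted fields are
#' summed. By default the sum is then normalized to unit maximum so that
#' sensitivities remain the only scale carrier; set `normalize = FALSE` for
#' absolute-intensity studies.
#'
#' @param use_layers named list of aligned [grid_layer()]s.
#' @param links data frame with columns `use`, `pressure`, `weight`
#'   (relative pressure weight in `[0, 1]`) and `distance_m` (propagation
#'   distance, meters `>= 0`).
#' @param pressure_id which pressure to assemble; at least one link must
#'   target it.
#' @param grid the analysis grid.
#' @param normalize divide by the field maximum (default `TRUE`).
#' @return a [grid_layer()] named after the pressure.
#' @export
pressure_map <- function(use_layers, links, pressure_id, grid,
                         normalize = TRUE) {
  links <- validate_links(links)
  sel <- links[links$pressure == pressure_id, , drop = FALSE]
  if (!nrow(sel)) stop("no pressure links target pressure '", pressure_id, "'")
  missing <- setdiff(sel$use, names(use_layers))
  if (length(missing))
    stop("pressure links reference unknown use(s): ",
         paste(missing, collapse = ", "))
  acc <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_len(nrow(sel))) {
    u <- use_layers[[sel$use[i]]]
    stopifnot_aligned(u, grid)
    sm <- gaussian_convolve(u, sel$distance_m[i])$values
    sm[is.na(sm)] <- 0
    acc <- acc + sel$weight[i] * sm
  }
  out <- grid_layer(pressure_id, acc, grid)
  if (normalize) out <- normalize_layer(out)
  out
}

validate_links <- function(links) {
  links <- as.data.frame(links)
  need <- c("use", "pressure", "weight", "distance_m")
  if (!all(need %in% names(links)))
    stop("pressure links need columns: ", paste(need, collapse = ", "))
  links <- links[need]
  links$use <- as.character(links$use)
  links$pressure <- as.character(links$pressure)
  links$weight <- as.numeric(links$weight)
  links$distance_m <- as.numeric(links$distance_m)
  rownames(links) <- NULL
  if (any(!is.finite(links$weight)) || any(!is.finite(links$distance_m)))
    stop("pressure link weights/distances must be finite")
  if (any(links$distance_m < 0))
    stop("pressure propagation distances must be >= 0")
  links
}

validate_sensitivities <- function(sens) {
  sens <- as.data.frame(sens)
  need <- c("pressure", "env", "sensitivity")
  if (!all(need %in% names(sens)))
    stop("sensitivities need columns: ", paste(need, collapse = ", "))
  sens <- sens[need]
  sens$pressure <- as.character(sens$pressure)
  sens$env <- as.character(sens$env)
  sens$sensitivity <- as.numeric(sens$sensitivity)
  rownames(sens) <- NULL
  if (any(!is.finite(sens$sensitivity)) || any(sens$sensitivity < 0))
    stop("sensitivities must be finite and >= 0")
  sens
}

#' Cumulative Effects Assessment map
#'
#' Combines pressure fields and environmental-component layers through the
#' sensitivity matrix. The partial effect of pressure `p` on receptor `e` in
#' a cell is `P_p * E_e * s(p, e)`; the cumulative score is the sum of all
#' partial effects. Environmental layers are expected already normalized to
#' `[0, 1]` (done at case-study load time); a larger maximum is an error,
#' never a silent rescale. Cells outside the area of analysis are nodata.
#'
#' @param pressure_maps named list of pressure [grid_layer()]s in `[0, 1]`.
#' @param env_layers named list of environmental [grid_layer()]s in `[0, 1]`.
#' @param sensitivities data frame with columns `pressure`, `env`,
#'   `sensitivity` (`>= 0`).
#' @param grid the analysis grid.
#' @return an object of class `cea_result`: `total_map` (grid layer),
#'   `partials` (named list of grid layers keyed `"pressure__env"`),
#'   `pressure_maps`, and the sensitivity table used.
#' @export
cea_map <- function(pressure_maps, env_layers, sensitivities, grid) {
  sens <- validate_sensitivities(sensitivities)
  bad_p <- setdiff(sens$pressure, names(pressure_maps))
  if (length(bad_p))
    stop("sensitivities reference unknown pressure(s): ",
         paste(bad_p, collapse = ", "))
  bad_e <- setdiff(sens$env, names(env_layers))
  if (length(bad_e))
    stop("sensitivities reference unknown environmental component(s): ",
         paste(bad_e, collapse = ", "))
  for (l in c(pressure_maps, env_layers)) {
    stopifnot_aligned(l, grid)
    if (max(l$values, na.rm = TRUE) > 1 + 1e-9)
      stop("layer '", l$name, "' exceeds 1; normalize inputs before cea_map")
  }
  total <- matrix(0, grid$nrow, grid$ncol)
  partials <- list()
  for (i in seq_len(nrow(sens))) {
    p <- sens$pressure[i]; e <- sens$env[i]; s <- sens$sensitivity[i]
    pv <- pressure_maps[[p]]$values; ev <- env_layers[[e]]$values
    pv[is.na(pv)] <- 0; ev[is.na(ev)] <- 0
    part <- s * pv * ev
    part[!grid$area_mask] <- NA_real_
    key <- paste0(p, "__", e)
    if (!is.null(partials[[key]]))
      stop("duplicate sensitivity entry for pressure '", p,
           "' and component '", e, "'")
    partials[[key]] <- grid_layer(key, part, grid)
    pp <- part; pp[is.na(pp)] <- 0
    total <- total + pp
  }
  total[!grid$area_mask] <- NA_real_
  structure(list(total_map = grid_layer("cea", total, grid),
                 partials = partials,
                 pressure_maps = pressure_maps,
                 sensitivities = sens),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("cea_result\n")
  print(x$total_map)
  cat(sprintf("  %d partial effect layer(s) (%d pressures x %d receptors in use)\n",
              length(x$partials), length(unique(x$sensitivities$pressure)),
              length(unique(x$sensitivities$env))))
  invisible(x)
}

#' Decompose a CEA result into contributions
#'
#' Tabulates summed partial effects over in-area cells, grouped by pressure,
#' by environmental component, or by (pressure, receptor) pair: the
#' statistical decomposition behind "which pressures drive the cumulative
#' score". Percentages are of the grand total and sum to 100 (all zeros when
#' the total is zero).
#'
#' @param result a [cea_map()] result.
#' @param group_by `"pair"`, `"pressure"` or `"env"`.
#' @return data frame with columns `group` (or `pressure`/`env` pair
#'   columns), `effect_sum`, `percent`, `cell_count` (in-area cells with a
#'   positive partial effect).
#' @export
partial_effects <- function(result, group_by = c("pair", "pressure", "env")) {
  group_by <- match.arg(group_by)
  if (!inherits(result, "cea_result")) stop("result must be a cea_result")
  keys <- names(result$partials)
  rows <- lapply(keys, function(k) {
    v <- result$partials[[k]]$values
    v <- v[!is.na(v)]
    pe <- strsplit(k, "__", fixed = TRUE)[[1L]]
    data.frame(pressure = pe[1L], env = pe[2L], effect_sum = sum(v),
               cell_count = sum(v > 0), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(pressure = character(), env = character(),
                      effect_sum = numeric(), cell_count = integer())
  if (group_by == "pressure") {
    tab <- stats::aggregate(cbind(effect_sum, cell_count) ~ pressure, tab, sum)
  } else if (group_by == "env") {
    tab <- stats::aggregate(cbind(effect_sum, cell_count) ~ env, tab, sum)
  }
  grand <- sum(tab$effect_sum)
  tab$percent <- if (grand > 0) 100 * tab$effect_sum / grand else
    rep(0, nrow(tab))
  tab
}
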