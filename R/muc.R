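VERTICAL_DOMAINS <- c("surface", "water_column", "seabed")
SPATIAL_DOMAINS  <- c("local", "large")
TEMPORAL_DOMAINS <- c("seasonal", "year_round")
MOBILITIES       <- c("mobile", "fixed")

#' COEXIST attributes of a human use
#'
#' The four expert-assigned traits from which pairwise conflict potential is
#' derived: the vertical domain(s) the use occupies (any non-empty subset of
#' surface / water column / seabed), its spatial domain (local footprint vs
#' large-scale), its temporal domain (seasonal vs year-round) and its
#' mobility (mobile vs fixed).
#'
#' @param vertical_domain character subset of
#'   `c("surface", "water_column", "seabed")`, non-empty.
#' @param spatial_domain `"local"` or `"large"`.
#' @param temporal_domain `"seasonal"` or `"year_round"`.
#' @param mobility `"mobile"` or `"fixed"`.
#' @return an object of class `use_attributes`.
#' @examples
#' use_attributes("seabed", "local", "year_round", "fixed")
#' @export
use_attributes <- function(vertical_domain, spatial_domain, temporal_domain,
                           mobility) {
  vertical_domain <- unique(as.character(vertical_domain))
  if (!length(vertical_domain) || !all(vertical_domain %in% VERTICAL_DOMAINS))
    stop("vertical_domain must be a non-empty subset of {",
         paste(VERTICAL_DOMAINS, collapse = ", "), "}")
  spatial_domain <- match.arg(spatial_domain, SPATIAL_DOMAINS)
  temporal_domain <- match.arg(temporal_domain, TEMPORAL_DOMAINS)
  mobility <- match.arg(mobility, MOBILITIES)
  structure(list(vertical_domain = vertical_domain,
                 spatial_domain = spatial_domain,
                 temporal_domain = temporal_domain,
                 mobility = mobility),
            class = "use_attributes")
}

#' Pairwise conflict rule set
#'
#' The scoring rules applied to a pair of uses: a vertical-overlap gate
#' (pairs whose vertical domains are disjoint cannot conflict) times three
#' additive components, each a symmetric 2x2 table over the corresponding
#' attribute vocabulary with values in `{0, 1, 2}`, so the attainable total
#' spans 0--6. The default tables encode the qualitative COEXIST logic —
#' persistent, spatially extensive, immobile co-located uses conflict most:
#'
#' * mobility: fixed+fixed = 2, fixed+mobile = 1, mobile+mobile = 0
#' * spatial: large+large = 2, large+local = 1, local+local = 0
#' * temporal: year_round+year_round = 2, year_round+seasonal = 1,
#'   seasonal+seasonal = 0
#'
#' The rule set is a plain configuration object, so a published calibration
#' can be substituted table-by-table.
#'
#' @param mobility,spatial,temporal symmetric numeric 2x2 matrices with
#'   dimnames over the attribute vocabularies and entries in `[0, 2]`.
#' @return an object of class `muc_ruleset`.
#' @export
default_ruleset <- function(mobility = NULL, spatial = NULL, temporal = NULL) {
  tbl <- function(levels, low_low, mixed, high_high) {
    m <- matrix(c(low_low, mixed, mixed, high_high), 2, 2,
                dimnames = list(levels, levels))
    m
  }
  rules <- list(
    mobility = mobility %||% tbl(MOBILITIES, 0, 1, 2),
    spatial  = spatial  %||% tbl(SPATIAL_DOMAINS, 0, 1, 2),
    temporal = temporal %||% tbl(TEMPORAL_DOMAINS, 0, 1, 2))
  for (nm in names(rules)) {
    m <- rules[[nm]]
    if (!is.matrix(m) || !all(dim(m) == 2) || !isSymmetric(unname(m)) ||
        any(m < 0) || any(m > 2))
      stop("rule table '", nm, "' must be a symmetric 2x2 matrix in [0, 2]")
  }
  structure(rules, class = "muc_ruleset")
}

#' Potential conflict score of a pair of uses
#'
#' Scores one unordered pair of uses from their attributes: 0 when their
#' vertical domains are disjoint (they cannot physically interfere),
#' otherwise the sum of the mobility, spatial and temporal rule-table
#' components. The score is symmetric in the pair and ranges from 0 (no
#' conflict) to 6 (very high conflict).
#'
#' @param a,b [use_attributes()] objects.
#' @param rules a [default_ruleset()].
#' @return integer score in `[0, 6]`.
#' @examples
#' att <- use_attributes("seabed", "large", "year_round", "fixed")
#' potential_conflict(att, att)  # 6 under the default rules
#' @export
potential_conflict <- function(a, b, rules = default_ruleset()) {
  if (!inherits(a, "use_attributes") || !inherits(b, "use_attributes"))
    stop("a and b must be use_attributes objects")
  if (!inherits(rules, "muc_ruleset")) stop("rules must be a muc_ruleset")
  gate <- as.integer(length(intersect(a$vertical_domain,
                                      b$vertical_domain)) > 0L)
  score <- gate * (rules$mobility[a$mobility, b$mobility] +
                   rules$spatial[a$spatial_domain, b$spatial_domain] +
                   rules$temporal[a$temporal_domain, b$temporal_domain])
  as.numeric(score)
}

#' Pairwise conflict matrix over a set of uses
#'
#' Applies [potential_conflict()] to every unordered pair of uses (the
#' diagonal holds each use's self score but is never accumulated into maps).
#'
#' @param attrs named list of [use_attributes()], one per use; names must be
#'   unique.
#' @param rules a [default_ruleset()].
#' @return symmetric numeric matrix with use names as dimnames, entries in
#'   `[0, 6]`, of class `conflict_matrix`.
#' @export
conflict_matrix <- function(attrs, rules = default_ruleset()) {
  nms <- names(attrs)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("attrs must be a named list of use_attributes")
  if (anyDuplicated(nms))
    stop("duplicate use names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  n <- length(attrs)
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n))
    for (j in i:n) {
      s <- potential_conflict(attrs[[i]], attrs[[j]], rules)
      m[i, j] <- s
      m[j, i] <- s
    }
  structure(m, class = c("conflict_matrix", "matrix"))
}

#' Presence/absence layers from intensity layers
#'
#' Thresholds use-intensity layers into the binary presence layers the MUC
#' model consumes: a cell hosts a use when its intensity strictly exceeds
#' `threshold`; nodata counts as absent.
#'
#' @param use_layers named list of aligned [grid_layer()]s.
#' @param threshold presence threshold (default 0: any positive intensity).
#' @return named list of binary grid layers.
#' @export
presence_layers <- function(use_layers, threshold = 0) {
  if (length(use_layers) > 1L)
    for (l in use_layers[-1L]) stopifnot_aligned(l, use_layers[[1L]]$grid)
  lapply(use_layers, function(l) {
    v <- l$values
    p <- !is.na(v) & v > threshold
    grid_layer(l$name, matrix(as.numeric(p), nrow(v), ncol(v)), l$grid)
  })
}

#' Maritime Use Conflict map
#'
#' Accumulates the total conflict score on every grid cell: the sum, over
#' all unordered pairs of uses both present in the cell, of their pairwise
#' potential conflict score. Cells outside the area of analysis are nodata.
#' Alongside the map, a pair-contribution table reports, per pair, the
#' number of in-area cells of co-occurrence and the total score contributed.
#'
#' @param presence named list of binary [grid_layer()]s (see
#'   [presence_layers()]).
#' @param matrix a [conflict_matrix()] covering every presence layer name.
#' @param grid the analysis grid.
#' @return an object of class `muc_result`: `score_map` (grid layer),
#'   `pair_contributions` (data frame `use_a, use_b, score_sum, cell_count`).
#' @export
muc_map <- function(presence, matrix, grid) {
  nms <- names(presence)
  if (length(nms) && !all(nms %in% rownames(matrix)))
    stop("presence layer(s) missing from conflict matrix: ",
         paste(setdiff(nms, rownames(matrix)), collapse = ", "))
  for (l in presence) stopifnot_aligned(l, grid)
  score <- base::matrix(0, grid$nrow, grid$ncol)
  pairs <- if (length(nms) >= 2L) utils::combn(nms, 2L, simplify = FALSE) else
    list()
  contrib <- data.frame(use_a = character(), use_b = character(),
                        score_sum = numeric(), cell_count = integer(),
                        stringsAsFactors = FALSE)
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    co <- presence[[a]]$values * presence[[b]]$values
    co[is.na(co)] <- 0
    co[!grid$area_mask] <- 0
    s <- matrix[a, b]
    score <- score + s * co
    contrib <- rbind(contrib, data.frame(
      use_a = a, use_b = b, score_sum = s * sum(co),
      cell_count = as.integer(sum(co)), stringsAsFactors = FALSE))
  }
  score[!grid$area_mask] <- NA_real_
  structure(list(score_map = grid_layer("muc", score, grid),
                 pair_contributions = contrib),
            class = "muc_result")
}

#' @export
print.muc_result <- function(x, ...) {
  cat("muc_result\n")
  print(x$score_map)
  cat(sprintf("  %d use pair(s), total score %g\n",
              nrow(x$pair_contributions), sum(x$pair_contributions$score_sum)))
  invisible(x)
}
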