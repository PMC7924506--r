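#' Gaussian-kernel smoothing of a grid layer
#'
#' Smooths a layer with an isotropic Gaussian kernel, the operator used to
#' propagate use intensities into pressure fields. `distance_m` is the
#' effective propagation radius: the kernel standard deviation is
#' `distance_m / 3`, so about 99.7% of the mass lies within the stated
#' distance. The kernel is truncated at four standard deviations and
#' renormalized to unit sum, so total mass is conserved up to boundary
#' truncation. Nodata cells contribute zero mass and the output is dense.
#'
#' @param layer a [grid_layer()].
#' @param distance_m effective propagation radius in meters, `>= 0`;
#'   `0` returns the input unchanged.
#' @return a [grid_layer()] on the same grid.
#' @export
gaussian_convolve <- function(layer, distance_m) {
  if (!is.numeric(distance_m) || length(distance_m) != 1L || is.na(distance_m))
    stop("distance_m must be a single number")
  if (distance_m < 0) stop("distance_m must be >= 0, got ", distance_m)
  if (distance_m == 0) return(layer)
  sigma <- distance_m / 3 / layer$grid$resolution  # in cell units
  radius <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  v <- layer$values
  v[is.na(v)] <- 0
  out <- conv_separable(v, k)
  grid_layer(layer$name, out, layer$grid)
}

# Separable 2D convolution with zero padding: one pass along columns of the
# matrix (x direction), one along rows (y direction).
conv_separable <- function(m, k) {
  conv_cols <- function(m, k) {
    r <- (length(k) - 1L) / 2L
    nr <- nrow(m); nc <- ncol(m)
    mp <- cbind(matrix(0, nr, r), m, matrix(0, nr, r))
    out <- matrix(0, nr, nc)
    for (s in seq_along(k))
      out <- out + k[s] * mp[, s:(s + nc - 1L), drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m, k)), k))
}

#' Normalize a layer to unit maximum
#'
#' Divides every value by the layer maximum (nodata excluded) so the output
#' maximum is 1. An all-zero layer is returned unchanged: zero layers
#' legitimately arise from empty use subsets and carry no scale to divide by.
#'
#' @param layer a [grid_layer()] with at least one non-nodata cell.
#' @return a [grid_layer()] with values in `[0, 1]`.
#' @export
normalize_layer <- function(layer) {
  v <- layer$values
  if (all(is.na(v))) stop("cannot normalize all-nodata layer '", layer$name, "'")
  mx <- max(v, na.rm = TRUE)
  if (mx == 0) return(layer)
  grid_layer(layer$name, v / mx, layer$grid)
}

#' Logarithmic scaling of a layer
#'
#' Cellwise `log(1 + value)`: monotone, maps 0 to 0, compresses heavy-tailed
#' intensity distributions (e.g. vessel-traffic densities) before
#' normalization. Nodata propagates.
#'
#' @param layer a [grid_layer()] with non-negative values.
#' @return a [grid_layer()].
#' @export
log_scale <- function(layer) {
  v <- layer$values
  if (any(v < 0, na.rm = TRUE))
    stop("log_scale requires non-negative values in layer '", layer$name, "'")
  grid_layer(layer$name, log1p(v), layer$grid)
}

#' Reclassify a layer into discrete classes
#'
#' Maps each cell to the class of its half-open interval: values below the
#' first break take `class_values[1]`, values in `[breaks[i], breaks[i+1])`
#' take `class_values[i + 1]`. Nodata propagates.
#'
#' @param layer a [grid_layer()].
#' @param breaks strictly increasing numeric break points.
#' @param class_values numeric classes, one more than `breaks`.
#' @return a [grid_layer()].
#' @export
reclassify <- function(layer, breaks, class_values) {
  if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  if (length(class_values) != length(breaks) + 1L)
    stop("need length(breaks) + 1 class_values, got ", length(class_values))
  v <- layer$values
  idx <- findInterval(v, breaks) + 1L
  out <- matrix(as.numeric(class_values)[idx], nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  grid_layer(layer$name, out, layer$grid)
}

#' Mask a layer
#'
#' Sets cells outside the mask to nodata; cells inside are unchanged. The
#' mask may be a logical matrix, a binary [grid_layer()] (nonzero = keep), or
#' the string `"area"` to use the grid's area-of-analysis mask.
#'
#' @param layer a [grid_layer()].
#' @param mask logical matrix aligned to the layer, a binary grid layer, or
#'   `"area"`.
#' @return a [grid_layer()].
#' @export
apply_mask <- function(layer, mask) {
  if (identical(mask, "area")) {
    keep <- layer$grid$area_mask
  } else if (inherits(mask, "grid_layer")) {
    stopifnot_aligned(mask, layer$grid)
    keep <- !is.na(mask$values) & mask$values != 0
  } else if (is.matrix(mask) && is.logical(mask)) {
    if (!all(dim(mask) == dim(layer$values)))
      stop("mask shape does not match layer '", layer$name, "'")
    keep <- mask
  } else stop("mask must be a logical matrix, grid_layer, or \"area\"")
  v <- layer$values
  v[!keep] <- NA_real_
  grid_layer(layer$name, v, layer$grid)
}

#' Linear rescale of a layer to a target range
#'
#' Affinely maps the observed value range `[min, max]` onto `[lo, hi]`.
#' A constant layer maps to `lo`. Nodata propagates.
#'
#' @param layer a [grid_layer()].
#' @param lo,hi target range bounds, `lo < hi`.
#' @return a [grid_layer()].
#' @export
rescale_layer <- function(layer, lo = 0, hi = 1) {
  if (!is.numeric(lo) || !is.numeric(hi) || hi <= lo)
    stop("need lo < hi")
  v <- layer$values
  if (all(is.na(v))) stop("cannot rescale all-nodata layer '", layer$name, "'")
  mn <- min(v, na.rm = TRUE); mx <- max(v, na.rm = TRUE)
  out <- if (mx == mn) ifelse(is.na(v), NA_real_, lo) else
    lo + (v - mn) / (mx - mn) * (hi - lo)
  grid_layer(layer$name, matrix(out, nrow(v), ncol(v)), layer$grid)
}
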