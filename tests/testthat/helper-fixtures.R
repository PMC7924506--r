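# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-cell loops, textbook formulas) and never call the code paths they
# check.

tiny_grid <- function(n = 20, res = 500, crs = "EPSG:3035")
  make_grid(c(0, 0, n * res, n * res), res, crs)

random_layer <- function(grid, name = "x", prop_na = 0) {
  v <- matrix(runif(grid$nrow * grid$ncol), grid$nrow, grid$ncol)
  if (prop_na > 0)
    v[sample(length(v), round(prop_na * length(v)))] <- NA_real_
  grid_layer(name, v, grid)
}

# rectangle polygon in bare GeoJSON-like structure
rect_polygon <- function(xmin, ymin, xmax, ymax)
  list(type = "Polygon",
       coordinates = list(list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                               c(xmin, ymax), c(xmin, ymin))))

# Ray-casting point-in-polygon oracle (even-odd rule), independent of the
# implementation's geometry backend.
oracle_point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- length(rx)
    hit <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      cross <- ((ry[i] > py) != (ry[j] > py)) &
        (px < (rx[j] - rx[i]) * (py - ry[i]) / (ry[j] - ry[i]) + rx[i])
      hit <- xor(hit, cross)
      j <- i
    }
    inside <- xor(inside, hit)
  }
  inside
}

# Naive per-cell MUC oracle: loop cells x unordered pairs.
oracle_muc <- function(presence, cm, grid) {
  nms <- names(presence)
  out <- matrix(NA_real_, grid$nrow, grid$ncol)
  for (r in seq_len(grid$nrow)) for (c in seq_len(grid$ncol)) {
    if (!grid$area_mask[r, c]) next
    s <- 0
    if (length(nms) >= 2)
      for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
        pi <- presence[[nms[i]]]$values[r, c]
        pj <- presence[[nms[j]]]$values[r, c]
        if (!is.na(pi) && !is.na(pj) && pi > 0 && pj > 0)
          s <- s + cm[nms[i], nms[j]]
      }
    out[r, c] <- s
  }
  out
}

# Naive per-cell CEA oracle: loop cells x sensitivity rows.
oracle_cea <- function(pmaps, envs, sens, grid) {
  out <- matrix(NA_real_, grid$nrow, grid$ncol)
  for (r in seq_len(grid$nrow)) for (c in seq_len(grid$ncol)) {
    if (!grid$area_mask[r, c]) next
    tot <- 0
    for (k in seq_len(nrow(sens))) {
      p <- pmaps[[sens$pressure[k]]]$values[r, c]
      e <- envs[[sens$env[k]]]$values[r, c]
      if (is.na(p)) p <- 0
      if (is.na(e)) e <- 0
      tot <- tot + sens$sensitivity[k] * p * e
    }
    out[r, c] <- tot
  }
  out
}

# Textbook type-7 quantile (linear interpolation between order statistics),
# written from the definition rather than via stats::quantile.
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Full COEXIST attribute vocabulary: all 7 non-empty vertical subsets x 2^3.
all_attribute_profiles <- function() {
  vsubsets <- unlist(lapply(1:3, function(k)
    combn(VERTICAL_DOMAINS <- c("surface", "water_column", "seabed"), k,
          simplify = FALSE)), recursive = FALSE)
  profiles <- list()
  for (v in vsubsets)
    for (s in c("local", "large"))
      for (t in c("seasonal", "year_round"))
        for (m in c("mobile", "fixed"))
          profiles[[length(profiles) + 1L]] <- use_attributes(v, s, t, m)
  profiles
}

local_case_study <- function(seed = 0, ...)
  generate_case_study(synthetic_spec(seed = seed, ...))

digest_file <- function(path) unname(tools::md5sum(path))

cli_script <- function()
  system.file("cli", "msptool.R", package = "mspgrid")

run_cli <- function(...) {
  args <- c(cli_script(), ...)
  status <- system2(file.path(R.home("bin"), "Rscript"), shQuote(args),
                    stdout = FALSE, stderr = FALSE)
  status
}
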