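test_that("grid construction follows the ceiling shape rule and validates inputs", {
  g <- make_grid(c(0, 0, 10000, 10000), 500, "EPSG:3035")
  expect_equal(c(g$nrow, g$ncol), c(20L, 20L))
  expect_true(all(g$area_mask))
  # non-divisible extent rounds up
  g2 <- make_grid(c(0, 0, 10250, 9100), 500, "EPSG:3035")
  expect_equal(c(g2$nrow, g2$ncol), c(ceiling(9100 / 500), ceiling(10250 / 500)))
  # re-creation is bit-identical
  expect_identical(make_grid(c(0, 0, 10000, 10000), 500, "EPSG:3035"), g)
  expect_error(make_grid(c(0, 0, 10000, 10000), 0, "EPSG:3035"), "resolution")
  expect_error(make_grid(c(0, 0, 10000, 10000), -5, "EPSG:3035"), "resolution")
  expect_error(make_grid(c(0, 0, 0, 10000), 500, "EPSG:3035"), "degenerate")
  expect_error(make_grid(c(0, 0, 1, 1), 0.5, "EPSG:4326"), "EPSG:4326")
})

test_that("area polygon masks cells by center containment", {
  left_half <- rect_polygon(0, 0, 5000, 10000)
  g <- make_grid(c(0, 0, 10000, 10000), 500, "EPSG:3035",
                 area_polygon = left_half)
  expect_equal(sum(g$area_mask), 200L)
  # oracle: ray-cast containment of cell centers
  xs <- rep(250 + 500 * (0:19), times = 20)
  ys <- rep(9750 - 500 * (0:19), each = 20)
  ring <- rbind(c(0, 0), c(5000, 0), c(5000, 10000), c(0, 10000))
  expect_equal(as.vector(t(g$area_mask)),
               oracle_point_in_rings(xs, ys, list(ring)))
})

test_that("rasterize covers cells whose centers fall inside polygons", {
  g <- tiny_grid()
  full <- rect_polygon(-1, -1, 10001, 10001)
  expect_true(all(rasterize_features(full, g)$values == 1))
  empty <- structure(list(crs = g$crs, features = list()),
                     class = "msp_features")
  expect_true(all(rasterize_features(empty, g)$values == 0))
  half <- rect_polygon(0, 0, 5000, 10000)
  expect_equal(sum(rasterize_features(half, g)$values), 200)
  # random rectangles against the center-containment oracle
  withr::with_seed(11, for (k in 1:10) {
    xy <- sort(runif(2, 0, 10000)); uv <- sort(runif(2, 0, 10000))
    lay <- rasterize_features(rect_polygon(xy[1], uv[1], xy[2], uv[2]), g)
    xs <- rep(250 + 500 * (0:19), times = 20)
    ys <- rep(9750 - 500 * (0:19), each = 20)
    ring <- rbind(c(xy[1], uv[1]), c(xy[2], uv[1]), c(xy[2], uv[2]),
                  c(xy[1], uv[2]))
    expect_equal(as.vector(t(lay$values)),
                 as.numeric(oracle_point_in_rings(xs, ys, list(ring))))
  })
})

test_that("rasterize burn mode sums values and is additive on disjoint sets", {
  g <- tiny_grid()
  f1 <- list(geometry = rect_polygon(0, 0, 4000, 10000),
             properties = list(v = 3))
  f2 <- list(geometry = rect_polygon(6000, 0, 10000, 10000),
             properties = list(v = 5))
  both <- rasterize_features(list(f1, f2), g, value_field = "v",
                             mode = "burn_value")
  one <- rasterize_features(list(f1), g, value_field = "v",
                            mode = "burn_value")
  two <- rasterize_features(list(f2), g, value_field = "v",
                            mode = "burn_value")
  expect_equal(both$values, one$values + two$values)
  expect_error(
    rasterize_features(list(list(geometry = rect_polygon(0, 0, 1, 1),
                                 properties = list())),
                       g, value_field = "v", mode = "burn_value"),
    "value_field")
  expect_error(rasterize_features(
    structure(list(crs = "EPSG:32633", features = list(f1)),
              class = "msp_features"), g), "crs")
})

test_that("points and lines burn the cells they touch", {
  g <- tiny_grid()
  pt <- list(type = "Point", coordinates = c(250, 9750))
  lay <- rasterize_features(pt, g)
  expect_equal(sum(lay$values), 1)
  expect_equal(lay$values[1, 1], 1)
  # horizontal line through row 10 touches all 20 columns
  ln <- list(type = "LineString",
             coordinates = list(c(0, 5250), c(9999, 5250)))
  lay <- rasterize_features(ln, g)
  expect_equal(sum(lay$values), 20)
  expect_true(all(lay$values[10, ] == 1))
})

test_that("gaussian convolution conserves mass and is isotropic", {
  g <- tiny_grid()
  m <- matrix(0, 20, 20); m[10, 10] <- 1
  src <- grid_layer("src", m, g)
  expect_identical(gaussian_convolve(src, 0), src)
  expect_error(gaussian_convolve(src, -1), ">= 0")
  sm <- gaussian_convolve(src, 2000)  # 4 sigma = 2667 m, well inside
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  expect_true(all(sm$values >= 0))
  # 90-degree rotation invariance of a centered point response
  g2 <- make_grid(c(0, 0, 10500, 10500), 500, "EPSG:3035")
  m2 <- matrix(0, 21, 21); m2[11, 11] <- 1
  sm2 <- gaussian_convolve(grid_layer("c", m2, g2), 2000)$values
  expect_equal(sm2, t(sm2))
  expect_equal(sm2, sm2[21:1, ])
  # random fields conserve mass when support is interior
  withr::with_seed(3, {
    m3 <- matrix(0, 20, 20)
    m3[8:13, 8:13] <- runif(36)
    sm3 <- gaussian_convolve(grid_layer("r", m3, g), 1000)
    expect_equal(sum(sm3$values), sum(m3), tolerance = 1e-6)
  })
})

test_that("normalize divides by the maximum and is idempotent", {
  g <- make_grid(c(0, 0, 1500, 500), 500, "EPSG:3035")
  lay <- grid_layer("x", matrix(c(0, 2, 4), 1, 3), g)
  expect_equal(as.vector(normalize_layer(lay)$values), c(0, 0.5, 1))
  zero <- grid_layer("z", matrix(0, 1, 3), g)
  expect_identical(normalize_layer(zero), zero)
  expect_error(normalize_layer(grid_layer("n", matrix(NA_real_, 1, 3), g)),
               "all-nodata")
  r <- random_layer(tiny_grid(), prop_na = 0.1)
  n1 <- normalize_layer(r)
  expect_identical(normalize_layer(n1)$values, n1$values)
  expect_true(all(n1$values >= 0 & n1$values <= 1, na.rm = TRUE))
})

test_that("log scaling is log1p with monotone order preservation", {
  g <- make_grid(c(0, 0, 1500, 500), 500, "EPSG:3035")
  expect_equal(log_scale(grid_layer("z", matrix(0, 1, 3), g))$values,
               matrix(0, 1, 3))
  expect_equal(log_scale(grid_layer("e", matrix(exp(1) - 1, 1, 3), g))$values,
               matrix(1, 1, 3))
  expect_error(log_scale(grid_layer("n", matrix(-1, 1, 3), g)),
               "non-negative")
  r <- random_layer(tiny_grid(), prop_na = 0.2)
  ls <- log_scale(r)
  expect_identical(is.na(ls$values), is.na(r$values))  # nodata preserved
  v <- r$values[!is.na(r$values)]; lv <- ls$values[!is.na(ls$values)]
  expect_identical(order(v), order(lv))
})

test_that("reclassify uses left-closed right-open intervals", {
  g <- make_grid(c(0, 0, 2000, 500), 500, "EPSG:3035")
  lay <- grid_layer("x", matrix(c(0.5, 1, 1.5, 2), 1, 4), g)
  out <- reclassify(lay, breaks = 1, class_values = c(0, 1))
  expect_equal(as.vector(out$values), c(0, 1, 1, 1))
  out <- reclassify(lay, breaks = c(1, 2), class_values = c(0, 5, 9))
  expect_equal(as.vector(out$values), c(0, 5, 5, 9))
  expect_error(reclassify(lay, c(2, 1), c(0, 1, 2)), "increasing")
  expect_error(reclassify(lay, c(1, 2), c(0, 1)), "class_values")
  # brute-force interval-membership oracle on a random layer
  withr::with_seed(5, {
    r <- random_layer(tiny_grid(), prop_na = 0.1)
    breaks <- c(0.25, 0.5, 0.75)
    classes <- c(10, 20, 30, 40)
    out <- reclassify(r, breaks, classes)
    exp <- r$values
    for (i in seq_along(exp)) {
      v <- r$values[i]
      if (is.na(v)) next
      k <- sum(v >= breaks) + 1
      exp[i] <- classes[k]
    }
    expect_equal(out$values, exp)
    expect_identical(is.na(out$values), is.na(r$values))
  })
})

test_that("masking replaces excluded cells with nodata", {
  g <- tiny_grid()
  r <- random_layer(g)
  expect_identical(apply_mask(r, matrix(TRUE, 20, 20))$values, r$values)
  allna <- apply_mask(r, matrix(FALSE, 20, 20))
  expect_true(all(is.na(allna$values)))
  withr::with_seed(9, {
    keep <- matrix(runif(400) > 0.5, 20, 20)
    out <- apply_mask(r, keep)
    expect_equal(sum(is.na(out$values)), sum(!keep))
    expect_identical(out$values[keep], r$values[keep])
  })
  # mask via binary layer and via the area mask
  bl <- grid_layer("m", matrix(rep(c(1, 0), 200), 20, 20), g)
  expect_equal(sum(is.na(apply_mask(r, bl)$values)), sum(bl$values == 0))
  expect_error(apply_mask(r, matrix(TRUE, 5, 5)), "shape")
})

test_that("ascii grid io round-trips layers bit-exactly", {
  withr::with_seed(21, {
    g <- tiny_grid()
    r <- random_layer(g, prop_na = 0.15)
    p <- withr::local_tempfile(fileext = ".asc")
    write_ascii_grid(r, p)
    back <- read_ascii_grid(p, grid = g, name = r$name)
    expect_identical(back$values, r$values)
    # geometry mismatch is an error
    g2 <- make_grid(c(0, 0, 5000, 5000), 500, "EPSG:3035")
    expect_error(read_ascii_grid(p, grid = g2), "not aligned")
  })
})
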