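# Helper: n-gon approximation of a circle.
.circle_poly <- function(cx, cz, radius, n = 2000) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  list(x = cx + radius * cos(th), z = cz + radius * sin(th))
}

test_that("circularity of analytic shapes (circle, square, rectangle)", {
  circ <- shape_metrics(shape_from_polygons(list(.circle_poly(0, 0, 0.37))))
  expect_equal(circ$circularity, 1, tolerance = 1e-3)
  expect_equal(circ$area, pi * 0.37^2, tolerance = 1e-3)

  sq <- shape_metrics(shape_from_polygons(list(
    list(x = c(0, 1, 1, 0), z = c(0, 0, 1, 1)))))
  expect_equal(sq$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)

  rect <- shape_metrics(shape_from_polygons(list(
    list(x = c(0, 2, 2, 0), z = c(0, 0, 1, 1)))))
  expect_equal(rect$circularity, 8 * pi / 36, tolerance = 1e-12)
})

test_that("circularity is scale-invariant and bounded by 1", {
  base <- list(x = c(0, 3, 3, 1, 1, 0), z = c(0, 0, 1, 1, 2, 2))  # L-shape
  m0 <- shape_metrics(shape_from_polygons(list(base)))
  for (c in c(1e-4, 0.7, 1, 13, 2.5e5)) {
    ms <- shape_metrics(shape_from_polygons(list(
      list(x = c * base$x, z = c * base$z))))
    expect_equal(ms$circularity, m0$circularity, tolerance = 1e-9)
    expect_equal(ms$area, c^2 * m0$area, tolerance = 1e-9)
  }
  expect_lt(m0$circularity, 1)
  expect_gt(m0$circularity, 0)
})

test_that("holes subtract area and add perimeter (even-odd nesting)", {
  outer <- .circle_poly(0, 0, 1)
  inner <- .circle_poly(0, 0, 0.5)
  m <- shape_metrics(shape_from_polygons(list(outer, inner)))
  expect_equal(m$area, pi * (1 - 0.25), tolerance = 1e-3)
  expect_equal(m$perimeter, 2 * pi * 1.5, tolerance = 1e-3)
  expect_equal(m$n_components, 1)

  # two disjoint components aggregate
  two <- shape_metrics(shape_from_polygons(list(
    .circle_poly(0, 0, 1), .circle_poly(5, 0, 1))))
  expect_equal(two$area, 2 * pi, tolerance = 1e-3)
  expect_equal(two$n_components, 2)
})

test_that("threshold extraction recovers an analytic level set", {
  geo <- build_probe_geometry("single_slot")
  # Gaussian bump centred in the tissue, away from the probe band; the
  # level set {f >= 1} is the circle of radius = 2 sd sqrt(ln 2)
  cz <- 0.075; sd <- 4e-3
  f <- function(p) 2 * exp(-((p[, 1])^2 + (p[, 2] - cz)^2) / (2 * sd^2))
  sh <- extract_threshold_shape(f, 1, geo, raster = 1e-4)
  m <- shape_metrics(sh)
  r_exact <- sd * sqrt(2 * log(2))
  expect_equal(m$area, pi * r_exact^2, tolerance = 2e-3)
  expect_equal(m$circularity, 1, tolerance = 2e-3)
  # mirrored about the axis: x-extents symmetric
  xs <- unlist(lapply(sh$polygons, `[[`, "x"))
  expect_equal(max(xs), -min(xs), tolerance = 1e-9)
})

test_that("probe band exclusion and the full-domain constant field", {
  geo <- build_probe_geometry("single_slot")
  sh <- extract_threshold_shape(function(p) rep(2, nrow(p)), 1, geo,
                                raster = 2e-4)
  m <- shape_metrics(sh)
  R <- geo$domain$tissue_radius; H <- geo$domain$tissue_height
  band <- 2 * geo$dims$r_catheter * geo$probe_tip
  expect_equal(m$area, 2 * R * H - band, tolerance = 0.01)
  # half-plane metrics are half of the symmetric totals (minus axis cut)
  expect_equal(m$area_half, m$area / 2, tolerance = 0.01)
})

test_that("empty shapes, resource guard and serialisation", {
  geo <- build_probe_geometry("single_slot")
  sh <- extract_threshold_shape(function(p) rep(0.1, nrow(p)), 1, geo,
                                raster = 4e-4)
  expect_true(sh$empty)
  expect_error(shape_metrics(sh), "empty shape")
  expect_identical(shape_to_wkt(sh), "MULTIPOLYGON EMPTY")

  expect_error(extract_threshold_shape(function(p) rep(2, nrow(p)), 1, geo,
                                       raster = 1e-6), "resource guard")

  tri <- shape_from_polygons(list(list(x = c(0, 1, 0), z = c(0, 0, 1))))
  expect_match(shape_to_wkt(tri), "^MULTIPOLYGON \\(\\(\\(0 0, 1 0, 0 1, 0 0\\)\\)\\)$")
  path <- tempfile(fileext = ".csv")
  write_shape_csv(tri, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("component", "x", "z"))
  expect_equal(nrow(df), 4)           # closed ring
  expect_equal(df$x[1], df$x[4])
})
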