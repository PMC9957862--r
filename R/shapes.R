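# Isocontour shape extraction and metrics.
#
# A scalar field on the axisymmetric half-plane is sampled onto a uniform
# raster, mirrored about the symmetry axis into a full (x, z) cross-section,
# and the region {field >= threshold} is traced as closed polygons with
# linear-interpolation isolines. The band occupied by the probe
# (|x| < r_catheter over the inserted length) is excluded; where the region
# abuts the catheter or the domain edge, those lines close the shape and
# count toward the perimeter. Metrics aggregate all disjoint components:
# area = sum of outer polygon areas minus hole areas (even-odd nesting),
# perimeter = total boundary length, circularity = 4*pi*area/perimeter^2
# (1 for a circle, < 1 otherwise, by the isoperimetric inequality).

#' Extract a thresholded, axis-mirrored field shape
#'
#' Samples `field_fun` on a uniform raster over the tissue bounding box,
#' mirrors it about the symmetry axis, masks the probe band, and traces the
#' closed isolines of the region `field >= threshold`.
#'
#' @param field_fun Function taking an n x 2 matrix of (r, z) points in m
#'   and returning the field value at each (NA treated as below threshold).
#' @param threshold Positive threshold in field units.
#' @param geometry The `mwa_geometry` the field lives on (sets the tissue
#'   bounding box and the probe band to exclude).
#' @param raster Raster spacing in m (default 0.2 mm). Values below 10 um
#'   are rejected as a resource guard.
#' @return An object of class `mwa_shape`: list of closed polygons
#'   (`x`, `z` in m), the threshold, raster size, and `empty` flag.
#' @export
extract_threshold_shape <- function(field_fun, threshold, geometry,
                                    raster = 2e-4) {
  stopifnot(threshold > 0)
  if (raster < 1e-5)
    stop("resource guard: raster spacing below 10 um (", raster, " m)")
  R <- geometry$domain$tissue_radius
  H <- geometry$domain$tissue_height
  xs <- seq(-R, R, by = raster)
  zs <- seq(0, H, by = raster)
  pts <- cbind(abs(rep(xs, times = length(zs))),
               rep(zs, each = length(xs)))
  vals <- field_fun(pts)
  f <- matrix(vals, length(xs), length(zs))
  f[is.na(f)] <- -Inf
  # probe band: |x| < r_catheter over the inserted length
  rc <- geometry$dims$r_catheter
  tip <- geometry$probe_tip
  f[abs(xs) < rc, zs <= tip] <- -Inf
  # pad with a below-threshold ring so all isolines close
  nx <- length(xs) + 2L; nz <- length(zs) + 2L
  fp <- matrix(-Inf, nx, nz)
  fp[2:(nx - 1L), 2:(nz - 1L)] <- f
  # -Inf breaks contourLines' linear interpolation; use a finite sentinel
  lo <- min(threshold - 1, min(vals, na.rm = TRUE) - 1, -1)
  fp[!is.finite(fp)] <- lo
  xp <- c(xs[1] - raster, xs, xs[length(xs)] + raster)
  zp <- c(zs[1] - raster, zs, zs[length(zs)] + raster)
  cl <- grDevices::contourLines(xp, zp, fp, levels = threshold)
  polys <- lapply(cl, function(p) list(x = p$x, z = p$y))
  # drop degenerate fragments (under 3 distinct points)
  polys <- Filter(function(p) length(p$x) >= 4, polys)
  structure(list(polygons = polys, threshold = threshold, raster = raster,
                 empty = length(polys) == 0L),
            class = "mwa_shape")
}

#' Construct a shape from explicit polygons
#'
#' Wraps closed polygons (each a list with `x` and `z` coordinate vectors,
#' first point repeated last or not) as an `mwa_shape` for [shape_metrics()];
#' mainly useful for testing metrics against analytic shapes.
#'
#' @param polygons List of polygons, each `list(x = ..., z = ...)`.
#' @return An `mwa_shape`.
#' @export
shape_from_polygons <- function(polygons) {
  polys <- lapply(polygons, function(p) {
    stopifnot(length(p$x) == length(p$z), length(p$x) >= 3)
    n <- length(p$x)
    if (p$x[1] != p$x[n] || p$z[1] != p$z[n]) {
      p$x <- c(p$x, p$x[1]); p$z <- c(p$z, p$z[1])
    }
    list(x = p$x, z = p$z)
  })
  structure(list(polygons = polys, threshold = NA_real_, raster = NA_real_,
                 empty = length(polys) == 0L),
            class = "mwa_shape")
}

# Shoelace signed area of one closed polygon.
.poly_signed_area <- function(x, z) {
  n <- length(x)
  sum(x[-n] * z[-1] - x[-1] * z[-n]) / 2
}

.poly_perimeter <- function(x, z) {
  sum(sqrt(diff(x)^2 + diff(z)^2))
}

# Even-odd point-in-polygon for one test point against one polygon.
.point_in_poly <- function(px, pz, x, z) {
  n <- length(x) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((z[i] > pz) != (z[j] > pz)) &&
        (px < (x[j] - x[i]) * (pz - z[i]) / (z[j] - z[i]) + x[i]))
      inside <- !inside
    j <- i
  }
  inside
}

#' Area, perimeter and circularity of a shape
#'
#' Aggregates all disjoint components of the mirrored cross-section shape:
#' total area (outer areas minus hole areas by even-odd nesting), total
#' perimeter (all boundaries, holes included), and circularity
#' `4 pi area / perimeter^2`. Half-plane (x > 0) area and perimeter are
#' reported alongside for transparency.
#'
#' @param shape An `mwa_shape`.
#' @return An object of class `mwa_shape_metrics`: `area` (m^2),
#'   `perimeter` (m), `circularity`, `n_components`, `area_half`,
#'   `perimeter_half`.
#' @export
shape_metrics <- function(shape) {
  if (shape$empty)
    stop("shape_metrics: empty shape (threshold above field maximum); ",
         "metrics undefined")
  np <- length(shape$polygons)
  absarea <- numeric(np); perim <- numeric(np); depth <- integer(np)
  for (i in seq_len(np)) {
    p <- shape$polygons[[i]]
    absarea[i] <- abs(.poly_signed_area(p$x, p$z))
    perim[i] <- .poly_perimeter(p$x, p$z)
  }
  # even-odd nesting depth: count enclosing polygons of a representative
  # vertex (offset slightly inward is unnecessary at even-odd parity since
  # contour polygons never share vertices on the raster)
  for (i in seq_len(np)) {
    p <- shape$polygons[[i]]
    for (j in seq_len(np)) {
      if (i == j) next
      q <- shape$polygons[[j]]
      if (.point_in_poly(p$x[1], p$z[1], q$x, q$z))
        depth[i] <- depth[i] + 1L
    }
  }
  sgn <- ifelse(depth %% 2L == 0L, 1, -1)
  area <- sum(sgn * absarea)
  perimeter <- sum(perim)
  # half-plane metrics: clip each polygon to x >= 0
  ah <- 0; ph <- 0
  for (i in seq_len(np)) {
    cp <- .clip_halfplane(shape$polygons[[i]])
    if (!is.null(cp)) {
      ah <- ah + sgn[i] * abs(.poly_signed_area(cp$x, cp$z))
      ph <- ph + .poly_perimeter(cp$x, cp$z)
    }
  }
  structure(list(area = area, perimeter = perimeter,
                 circularity = 4 * pi * area / perimeter^2,
                 n_components = sum(depth %% 2L == 0L),
                 area_half = ah, perimeter_half = ph),
            class = "mwa_shape_metrics")
}

# Sutherland-Hodgman clip of one closed polygon to the half-plane x >= 0.
.clip_halfplane <- function(p) {
  x <- p$x; z <- p$z
  n <- length(x)
  ox <- numeric(0); oz <- numeric(0)
  for (i in seq_len(n - 1L)) {
    x1 <- x[i]; z1 <- z[i]; x2 <- x[i + 1L]; z2 <- z[i + 1L]
    in1 <- x1 >= 0; in2 <- x2 >= 0
    if (in1) { ox <- c(ox, x1); oz <- c(oz, z1) }
    if (in1 != in2) {
      t <- x1 / (x1 - x2)
      ox <- c(ox, 0); oz <- c(oz, z1 + t * (z2 - z1))
    }
  }
  if (length(ox) < 3) return(NULL)
  list(x = c(ox, ox[1]), z = c(oz, oz[1]))
}

#' Shape as well-known-text polygons
#'
#' Serialises all components as a WKT `MULTIPOLYGON` (each component a
#' single-ring polygon; nesting is not re-encoded, matching the aggregate
#' metric convention).
#'
#' @param shape An `mwa_shape`.
#' @return A WKT string.
#' @export
shape_to_wkt <- function(shape) {
  if (shape$empty) return("MULTIPOLYGON EMPTY")
  rings <- vapply(shape$polygons, function(p) {
    x <- p$x; z <- p$z
    n <- length(x)
    if (x[1] != x[n] || z[1] != z[n]) { x <- c(x, x[1]); z <- c(z, z[1]) }
    paste0("((", paste(sprintf("%.9g %.9g", x, z), collapse = ", "), "))")
  }, character(1))
  paste0("MULTIPOLYGON (", paste(rings, collapse = ", "), ")")
}

#' Write shape outlines as closed polyline CSV
#'
#' One row per vertex with columns `component`, `x`, `z`; each component's
#' first vertex is repeated at its end so the polylines are closed.
#'
#' @param shape An `mwa_shape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shape_csv <- function(shape, path) {
  rows <- list()
  for (i in seq_along(shape$polygons)) {
    p <- shape$polygons[[i]]
    x <- p$x; z <- p$z
    n <- length(x)
    if (n && (x[1] != x[n] || z[1] != z[n])) { x <- c(x, x[1]); z <- c(z, z[1]) }
    rows[[i]] <- data.frame(component = i, x = x, z = z)
  }
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(component = integer(0), x = numeric(0), z = numeric(0))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @exportS3Method print mwa_shape
print.mwa_shape <- function(x, ...) {
  cat(sprintf("mwablate shape: %d component(s), threshold %g, raster %g m%s\n",
              length(x$polygons), x$threshold, x$raster,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' @exportS3Method print mwa_shape_metrics
print.mwa_shape_metrics <- function(x, ...) {
  cat(sprintf("area %.4g m^2 (half-plane %.4g), perimeter %.4g m, circularity %.4f, %d component(s)\n",
              x$area, x$area_half, x$perimeter, x$circularity, x$n_components))
  invisible(x)
}
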