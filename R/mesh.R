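#' Mesh size controls
#'
#' Controls for the graded structured triangulation. Sizes are element
#' diameters in m: `h_fine` is the target at the slot (and other radiating
#' feature) surfaces, `h_far` at the outer tissue boundary. `grading` is the
#' growth of the target size per unit distance away from refined features
#' (0.35 means neighbouring element sizes grow by about a factor 1.35).
#' `wavelength_points` caps the in-tissue element diameter at
#' lambda_tissue / wavelength_points, with the tissue wavelength evaluated
#' at the reference temperature.
#'
#' @param h_fine Fine size near slots/tip in m (default 0.1 mm).
#' @param h_far Far-field size in m (default 2 mm).
#' @param grading Dimensionless grading slope (default 0.35).
#' @param wavelength_points Minimum resolution points per in-tissue
#'   wavelength (default 10).
#' @return An object of class `mwa_mesh_controls`.
#' @export
mesh_controls <- function(h_fine = 1e-4, h_far = 2e-3, grading = 0.35,
                          wavelength_points = 10) {
  stopifnot(h_fine > 0, h_fine <= h_far, grading > 0, wavelength_points >= 5)
  structure(list(h_fine = h_fine, h_far = h_far, grading = grading,
                 wavelength_points = wavelength_points),
            class = "mwa_mesh_controls")
}

#' Assemble a geometry from rectangles (fixture helper)
#'
#' Builds a minimal `mwa_geometry` from named axis-aligned rectangles.
#' Intended for analytic test fixtures (unit squares, coax strips, uniform
#' discs); [build_probe_geometry()] is the constructor for real probes.
#'
#' @param regions Named list; each element a list of rectangles created as
#'   `list(r0=, r1=, z0=, z1=)` (names give the material region).
#' @param boundaries data.frame with columns `tag`, `r0`, `r1`, `z0`, `z1`
#'   describing tagged axis-aligned exterior segments. Untagged exterior
#'   edges default to PEC.
#' @param holes Optional named list of excluded rectangles (PEC interiors).
#' @return An `mwa_geometry`.
#' @export
geometry_from_rects <- function(regions, boundaries, holes = list()) {
  regions <- lapply(names(regions), function(nm) {
    lapply(regions[[nm]], function(rc)
      .rect(nm, rc$r0, rc$r1, rc$z0, rc$z1))
  }) |> stats::setNames(names(regions))
  holes <- lapply(names(holes), function(nm) {
    rc <- holes[[nm]]
    .rect(nm, rc$r0, rc$r1, rc$z0, rc$z1)
  }) |> stats::setNames(names(holes))
  structure(list(concept = "fixture", dims = NULL, domain = NULL,
                 regions = regions, holes = holes, boundaries = boundaries,
                 probe_tip = NA_real_, cap_top = NA_real_),
            class = "mwa_geometry")
}

#' Straight coaxial line fixture
#'
#' An annular dielectric strip (no slot, no tissue): the TEM field in this
#' geometry is known analytically (E_r = A0/r decaying as exp(-gamma z)),
#' which makes it the package's primary electromagnetic oracle. The side
#' walls are PEC; the far end is either matched (absorbing, reflection about
#' zero) or shorted (PEC, total reflection).
#'
#' @param r_i,r_o Inner/outer radii of the dielectric annulus in m.
#' @param len Line length in m.
#' @param termination `"absorbing"` or `"short"`.
#' @param region Material region name for the fill (default
#'   `"coax_dielectric"`).
#' @return An `mwa_geometry`.
#' @export
coax_line_geometry <- function(r_i = 0.135e-3, r_o = 0.335e-3, len = 0.02,
                               termination = c("absorbing", "short"),
                               region = "coax_dielectric") {
  termination <- match.arg(termination)
  regions <- list(list(list(r0 = r_i, r1 = r_o, z0 = 0, z1 = len)))
  names(regions) <- region
  boundaries <- data.frame(tag = "port", r0 = r_i, r1 = r_o, z0 = 0, z1 = 0)
  if (termination == "absorbing")
    boundaries <- rbind(boundaries,
      data.frame(tag = "outer_absorbing", r0 = r_i, r1 = r_o, z0 = len, z1 = len))
  # side walls (and a shorted far end) fall through to the PEC default
  geometry_from_rects(regions, boundaries)
}

# In-tissue wavelength (m) at the reference temperature.
.tissue_wavelength <- function(materials, frequency) {
  eps <- permittivity_at_temperature(materials$T_ref, materials$sigmoid)
  sig <- conductivity_at_temperature(materials$T_ref, materials$sigmoid)
  w <- 2 * pi * frequency
  k <- (w / .c0) * sqrt(complex(real = eps, imaginary = -sig / (w * .eps0)))
  2 * pi / Re(k)
}

# 1D size field: min over fine boxes of (h_box + grading * distance to box),
# capped at h_cap. boxes: data.frame(lo, hi, h).
.size_field <- function(boxes, grading, h_cap) {
  force(boxes); force(grading); force(h_cap)
  function(x) {
    h <- rep(h_cap, length(x))
    if (!is.null(boxes) && nrow(boxes) > 0) {
      for (i in seq_len(nrow(boxes))) {
        d <- pmax(0, pmax(boxes$lo[i] - x, x - boxes$hi[i]))
        h <- pmin(h, boxes$h[i] + grading * d)
      }
    }
    h
  }
}

# Graded 1D point distribution: breaks at all feature coordinates, points
# placed at equal increments of the cumulative density integral(1/h).
.graded_points <- function(features, sizef) {
  features <- sort(unique(features))
  pts <- features[1]
  for (k in seq_len(length(features) - 1L)) {
    a <- features[k]; b <- features[k + 1L]
    xs <- seq(a, b, length.out = 201)
    dens <- 1 / sizef(xs)
    cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs)))
    n <- max(1L, ceiling(cum[length(cum)] - 1e-9))
    lev <- seq(0, cum[length(cum)], length.out = n + 1L)
    xin <- approx(cum, xs, xout = lev[-c(1, length(lev))], ties = "ordered")$y
    pts <- c(pts, xin, b)
  }
  pts
}

# Fine-zone boxes derived from the geometry's radiating features.
.refinement_boxes <- function(geometry, controls) {
  hf <- controls$h_fine / sqrt(2)   # directional spacing for diameter h_fine
  hm <- 2.5 * controls$h_fine / sqrt(2)
  ha <- 5 * controls$h_fine / sqrt(2)
  rb <- NULL; zb <- NULL
  feat_z <- NULL

  slot <- geometry$regions$slot_fill
  rc <- if (!is.null(geometry$dims)) geometry$dims$r_catheter else NA
  for (s in slot) {
    zb <- rbind(zb, data.frame(lo = s$z0 - 5e-4, hi = s$z1 + 5e-4, h = hf))
    rb <- rbind(rb, data.frame(lo = s$r0 - 2e-4, hi = rc + 3e-4, h = hf))
    feat_z <- c(feat_z, s$z0, s$z1)
  }
  if (!is.na(geometry$cap_top)) {
    # shorting disc / tip cap band
    zb <- rbind(zb, data.frame(lo = geometry$cap_top - 1.5e-3,
                               hi = geometry$probe_tip + 1e-3, h = hm))
    feat_z <- c(feat_z, geometry$cap_top, geometry$probe_tip)
  }
  if (!is.null(geometry$holes$sleeve)) {
    sl <- geometry$holes$sleeve
    zb <- rbind(zb,
      data.frame(lo = sl$z0 - 1e-3, hi = sl$z0 + 1e-3, h = hm),
      data.frame(lo = sl$z1 - 1e-3, hi = sl$z1 + 1e-3, h = hm))
    feat_z <- c(feat_z, sl$z0, sl$z1)
  }
  if (geometry$concept == "monopole") {
    # exposed radiating section: outer conductor end to the cap
    oc <- geometry$holes$outer_conductor_1
    zb <- rbind(zb, data.frame(lo = oc$z1 - 1e-3,
                               hi = geometry$probe_tip + 1e-3, h = hm))
    rb <- rbind(rb, data.frame(lo = oc$r0 - 2e-4, hi = rc + 3e-4, h = hm))
    feat_z <- c(feat_z, oc$z1)
  }
  if (!is.null(feat_z)) {
    # active near-field zone around the radiating structures
    zb <- rbind(zb, data.frame(lo = min(feat_z) - 12e-3,
                               hi = max(feat_z, geometry$probe_tip) + 8e-3,
                               h = ha))
  }
  if (!is.na(rc)) {
    # resolve the thin probe layers radially
    rb <- rbind(rb, data.frame(lo = 0, hi = rc, h = 0.8 * controls$h_fine))
  }
  list(r = rb, z = zb)
}

#' Generate a conforming triangular mesh
#'
#' Triangulates an `mwa_geometry` with a deterministic graded
#' tensor-product grid: all material interface coordinates become grid
#' lines, 1D spacings follow a graded size field (fine at the slot/tip,
#' growing geometrically to the far size, capped at the in-tissue
#' wavelength over `wavelength_points`), and every grid cell is split into
#' two triangles. Conductor holes are excluded; their surfaces become
#' PEC-tagged boundary edges. Re-running with identical inputs yields an
#' identical mesh.
#'
#' @param geometry An `mwa_geometry`.
#' @param controls A [mesh_controls()] object.
#' @param materials Materials (for the wavelength cap); `NULL` disables it.
#' @param frequency Operating frequency in Hz (for the wavelength cap).
#' @return An object of class `mwa_mesh`: `vertices` (n x 2, (r, z) in m),
#'   `triangles` (m x 3 vertex indices, counter-clockwise), `region_id`
#'   (integer per triangle into `region_names`), `boundary_edges`
#'   (data.frame `v1`, `v2`, `tag`), plus the structured-grid metadata used
#'   for fast point location.
#' @export
generate_mesh <- function(geometry, controls = mesh_controls(),
                          materials = default_materials(),
                          frequency = 2.45e9) {
  stopifnot(inherits(geometry, "mwa_geometry"),
            inherits(controls, "mwa_mesh_controls"))
  h_cap <- controls$h_far / sqrt(2)
  if (!is.null(materials) && !is.null(frequency)) {
    lam <- .tissue_wavelength(materials, frequency)
    h_cap <- min(h_cap, lam / controls$wavelength_points / sqrt(2))
  }

  all_rects <- c(unlist(geometry$regions, recursive = FALSE), geometry$holes)
  rfeat <- sort(unique(unlist(lapply(all_rects, function(x) c(x$r0, x$r1)))))
  zfeat <- sort(unique(unlist(lapply(all_rects, function(x) c(x$z0, x$z1)))))
  boxes <- .refinement_boxes(geometry, controls)
  rpts <- .graded_points(rfeat, .size_field(boxes$r, controls$grading, h_cap))
  zpts <- .graded_points(zfeat, .size_field(boxes$z, controls$grading, h_cap))
  nr <- length(rpts); nz <- length(zpts)

  # cell -> region / hole assignment by centre lookup
  rc_mid <- (rpts[-1] + rpts[-nr]) / 2
  zc_mid <- (zpts[-1] + zpts[-nz]) / 2
  ncr <- nr - 1L; ncz <- nz - 1L
  region_names <- names(geometry$regions)
  cell_reg <- matrix(0L, ncr, ncz)  # 0 = unassigned, -1 = hole
  assign_rect <- function(rc, code) {
    ir <- which(rc_mid > rc$r0 & rc_mid < rc$r1)
    iz <- which(zc_mid > rc$z0 & zc_mid < rc$z1)
    if (length(ir) == 0 || length(iz) == 0)
      stop("unmeshable geometry: region '", rc$name,
           "' contains no cell (degenerate sliver)")
    cell_reg[ir, iz] <<- code
  }
  for (k in seq_along(region_names))
    for (rc in geometry$regions[[k]]) assign_rect(rc, k)
  for (h in geometry$holes) assign_rect(h, -1L)
  if (any(cell_reg == 0L))
    stop("unmeshable geometry: cells not covered by any region or hole")

  # triangles: split each non-hole cell along the (lo,lo)-(hi,hi) diagonal
  cell_idx <- which(cell_reg > 0L)
  ir <- ((cell_idx - 1L) %% ncr) + 1L
  iz <- ((cell_idx - 1L) %/% ncr) + 1L
  vid <- function(i, j) (j - 1L) * nr + i   # grid vertex id, ordered by z-level
  v00 <- vid(ir, iz); v10 <- vid(ir + 1L, iz)
  v01 <- vid(ir, iz + 1L); v11 <- vid(ir + 1L, iz + 1L)
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  reg <- c(cell_reg[cell_idx], cell_reg[cell_idx])
  # interleave so cell k owns triangles (2k-1, 2k)
  ntri_cells <- length(cell_idx)
  ord <- as.vector(rbind(seq_len(ntri_cells), seq_len(ntri_cells) + ntri_cells))
  tris <- tris[ord, , drop = FALSE]
  reg <- reg[ord]
  cell_tri <- matrix(NA_integer_, ncr, ncz)
  cell_tri[cell_idx] <- seq(1L, by = 2L, length.out = ntri_cells)

  # drop unreferenced grid vertices, renumber (keeps z-level ordering)
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nr * nz)
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3)
  gi <- ((used - 1L) %% nr) + 1L
  gj <- ((used - 1L) %/% nr) + 1L
  vertices <- cbind(r = rpts[gi], z = zpts[gj])

  # boundary edges: those appearing in exactly one triangle
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ekey)
  bkey <- names(tab)[tab == 1L]
  bidx <- match(bkey, ekey)
  be <- e[bidx, , drop = FALSE]

  # tag by midpoint lookup against the geometry's boundary segments
  mid_r <- (vertices[be[, 1], 1] + vertices[be[, 2], 1]) / 2
  mid_z <- (vertices[be[, 1], 2] + vertices[be[, 2], 2]) / 2
  tol <- 1e-12 + 1e-9 * max(rpts[nr], zpts[nz])
  tags <- rep("pec", nrow(be))
  bd <- geometry$boundaries
  for (i in seq_len(nrow(bd))) {
    if (bd$z0[i] == bd$z1[i]) {     # horizontal segment
      onit <- abs(mid_z - bd$z0[i]) < tol &
        mid_r > bd$r0[i] - tol & mid_r < bd$r1[i] + tol
    } else {                         # vertical segment
      onit <- abs(mid_r - bd$r0[i]) < tol &
        mid_z > bd$z0[i] - tol & mid_z < bd$z1[i] + tol
    }
    tags[onit] <- bd$tag[i]
  }
  boundary_edges <- data.frame(v1 = be[, 1], v2 = be[, 2], tag = tags)

  structure(list(vertices = vertices, triangles = tris,
                 region_id = reg, region_names = region_names,
                 boundary_edges = boundary_edges,
                 rbreaks = rpts, zbreaks = zpts,
                 cell_tri = cell_tri, grid_used = remap,
                 controls = controls, cache = new.env(parent = emptyenv())),
            class = "mwa_mesh")
}

# Locate points in a structured mesh: returns triangle index (NA outside the
# meshed domain) for query points (n x 2).
.mesh_locate <- function(mesh, pts) {
  if (is.null(mesh$cell_tri))
    stop("point location requires a structured mesh from generate_mesh()")
  nr <- length(mesh$rbreaks); nz <- length(mesh$zbreaks)
  ir <- findInterval(pts[, 1], mesh$rbreaks, rightmost.closed = TRUE)
  iz <- findInterval(pts[, 2], mesh$zbreaks, rightmost.closed = TRUE)
  ok <- ir >= 1L & ir <= nr - 1L & iz >= 1L & iz <= nz - 1L
  tri <- rep(NA_integer_, nrow(pts))
  if (any(ok)) {
    t1 <- mesh$cell_tri[cbind(ir[ok], iz[ok])]
    xi <- (pts[ok, 1] - mesh$rbreaks[ir[ok]]) /
      (mesh$rbreaks[ir[ok] + 1L] - mesh$rbreaks[ir[ok]])
    eta <- (pts[ok, 2] - mesh$zbreaks[iz[ok]]) /
      (mesh$zbreaks[iz[ok] + 1L] - mesh$zbreaks[iz[ok]])
    tri[ok] <- ifelse(xi >= eta, t1, t1 + 1L)  # diagonal (lo,lo)-(hi,hi)
  }
  tri
}

# Signed triangle areas (positive = counter-clockwise).
.tri_areas <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  0.5 * ((v[t[, 2], 1] - v[t[, 1], 1]) * (v[t[, 3], 2] - v[t[, 1], 2]) -
         (v[t[, 3], 1] - v[t[, 1], 1]) * (v[t[, 2], 2] - v[t[, 1], 2]))
}

#' @exportS3Method print mwa_mesh
print.mwa_mesh <- function(x, ...) {
  cat("mwablate mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  a <- .tri_areas(x)
  cat(sprintf("  half-plane area: %.6g m^2; min/max triangle area: %.3g / %.3g m^2\n",
              sum(a), min(a), max(a)))
  cat("  regions:", paste(sprintf("%s (%d)", x$region_names,
                                  tabulate(x$region_id, length(x$region_names))),
                          collapse = ", "), "\n")
  cat("  boundary edges:",
      paste(sprintf("%s (%d)", names(table(x$boundary_edges$tag)),
                    as.integer(table(x$boundary_edges$tag))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a mesh in Gmsh ASCII v2.2 format
#'
#' Physical groups carry the region names (surfaces) and boundary tags
#' (lines), so external meshers and viewers can interoperate.
#'
#' @param mesh An `mwa_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tag_names <- sort(unique(mesh$boundary_edges$tag))
  nreg <- length(mesh$region_names)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$PhysicalNames",
               as.character(length(tag_names) + nreg)), con)
  for (i in seq_along(tag_names))
    writeLines(sprintf('1 %d "%s"', i, tag_names[i]), con)
  for (i in seq_len(nreg))
    writeLines(sprintf('2 %d "%s"', length(tag_names) + i,
                       mesh$region_names[i]), con)
  writeLines("$EndPhysicalNames", con)
  nv <- nrow(mesh$vertices)
  writeLines(c("$Nodes", as.character(nv)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nv),
                     mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines("$EndNodes", con)
  ne <- nrow(mesh$boundary_edges); nt <- nrow(mesh$triangles)
  writeLines(c("$Elements", as.character(ne + nt)), con)
  etag <- match(mesh$boundary_edges$tag, tag_names)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(ne), etag, etag,
                     mesh$boundary_edges$v1, mesh$boundary_edges$v2), con)
  rtag <- length(tag_names) + mesh$region_id
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", ne + seq_len(nt), rtag, rtag,
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh ASCII v2.2 format
#'
#' Inverse of [write_mesh_msh()]. The structured-grid metadata is not part
#' of the interchange format, so meshes read back support assembly but not
#' the fast structured point location.
#'
#' @param path Input file path.
#' @return An `mwa_mesh`.
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("msh: missing section ", name)
    lines[(i0 + 1):(i1 - 1)]
  }
  pn <- sec("PhysicalNames")[-1]
  pn_sp <- strsplit(pn, " ")
  pdim <- vapply(pn_sp, function(x) as.integer(x[1]), 0L)
  pid <- vapply(pn_sp, function(x) as.integer(x[2]), 0L)
  pname <- gsub('"', "", vapply(pn_sp, function(x) paste(x[-(1:2)], collapse = " "), ""))
  nd <- sec("Nodes")[-1]
  ndm <- matrix(as.numeric(unlist(strsplit(nd, " "))), ncol = 4, byrow = TRUE)
  vertices <- cbind(r = ndm[, 2], z = ndm[, 3])
  el <- sec("Elements")[-1]
  ell <- strsplit(el, " ")
  etype <- vapply(ell, function(x) as.integer(x[2]), 0L)
  ephys <- vapply(ell, function(x) as.integer(x[4]), 0L)
  lines_el <- ell[etype == 1L]
  tri_el <- ell[etype == 2L]
  triangles <- t(vapply(tri_el, function(x) as.integer(x[6:8]), integer(3)))
  tri_phys <- ephys[etype == 2L]
  region_names <- pname[pdim == 2L][order(pid[pdim == 2L])]
  region_id <- match(pname[match(tri_phys, pid)], region_names)
  be <- t(vapply(lines_el, function(x) as.integer(x[6:7]), integer(2)))
  btag <- pname[match(ephys[etype == 1L], pid)]
  structure(list(vertices = vertices, triangles = triangles,
                 region_id = region_id, region_names = region_names,
                 boundary_edges = data.frame(v1 = be[, 1], v2 = be[, 2],
                                             tag = btag),
                 rbreaks = NULL, zbreaks = NULL, cell_tri = NULL,
                 controls = NULL, cache = new.env(parent = emptyenv())),
            class = "mwa_mesh")
}
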