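#' Probe concepts
#'
#' The four interstitial antenna concepts simulated by the package:
#' `"monopole"` (M, outer conductor stripped near the tip), `"single_slot"`
#' (SS, one ring gap in the outer conductor), `"dual_slot"` (DS, two ring
#' gaps) and `"sleeve_single_slot"` (SSS, single slot plus a floating
#' conducting sleeve inside the catheter).
#'
#' @return Character vector of the four concept names.
#' @export
probe_concepts <- function() {
  c("monopole", "single_slot", "dual_slot", "sleeve_single_slot")
}

.match_concept <- function(concept) {
  match.arg(concept, probe_concepts())
}

#' Default probe dimensions
#'
#' Common coaxial/catheter dimensions shared by all four probe concepts,
#' plus concept-specific feature placements. The coax radii (inner conductor
#' 0.135 mm, dielectric 0.335 mm, outer conductor 0.46 mm, catheter
#' 0.895 mm), the 1 mm slot width, the 0.15 mm sleeve thickness and the
#' 70 mm probe length are the standard published values for this probe
#' family. Feature placements that are only available as drawings in the
#' source literature are shipped as documented, configurable defaults:
#' slot centre 5 mm from the probe tip, 8 mm centre-to-centre slot
#' separation (DS), a 15 mm sleeve starting 10 mm above the slot with a
#' 0.1 mm radial gap (SSS), and a 10 mm exposed monopole section (M).
#'
#' All lengths are stored in metres.
#'
#' @param concept One of [probe_concepts()].
#' @return An object of class `mwa_dimensions` (named list of lengths in m).
#' @export
#' @examples
#' default_dimensions("single_slot")$r_outer  # 0.46 mm
default_dimensions <- function(concept = "single_slot") {
  concept <- .match_concept(concept)
  mm <- 1e-3
  dims <- list(
    r_inner      = 0.135 * mm,
    r_dielectric = 0.335 * mm,
    r_outer      = 0.46 * mm,
    r_catheter   = 0.895 * mm,
    slot_width   = 1 * mm,
    sleeve_thickness = 0.15 * mm,
    probe_length = 70 * mm,
    slot_tip_offset = 5 * mm,       # slot centre to probe tip
    slot_separation = 8 * mm,       # DS only, centre-to-centre
    sleeve_gap = 0.1 * mm,          # SSS: outer conductor to sleeve
    sleeve_start_offset = 10 * mm,  # SSS: slot top edge to sleeve bottom edge
    sleeve_length = 15 * mm,        # SSS
    monopole_exposed_length = 10 * mm, # M only
    short_thickness = 0.3 * mm      # conductor disc shorting the coax at the tip
  )
  if (concept == "monopole") {
    dims$slot_width <- NA_real_
    dims$slot_tip_offset <- NA_real_
  }
  if (concept != "dual_slot") dims$slot_separation <- NA_real_
  if (concept != "sleeve_single_slot") {
    dims$sleeve_thickness <- NA_real_
    dims$sleeve_gap <- NA_real_
    dims$sleeve_start_offset <- NA_real_
    dims$sleeve_length <- NA_real_
  }
  if (concept != "monopole") dims$monopole_exposed_length <- NA_real_
  structure(c(list(concept = concept), dims), class = "mwa_dimensions")
}

.validate_dimensions <- function(dims) {
  with(dims, {
    stopifnot(
      0 < r_inner, r_inner < r_dielectric,
      r_dielectric < r_outer, r_outer < r_catheter,
      probe_length > 0
    )
    if (dims$concept != "monopole") {
      stopifnot(slot_width > 0, slot_tip_offset > slot_width / 2,
                slot_tip_offset + slot_width / 2 < probe_length)
    }
    if (dims$concept == "sleeve_single_slot") {
      stopifnot(sleeve_thickness > 0, sleeve_gap > 0, sleeve_length > 0)
      if (r_outer + sleeve_gap + sleeve_thickness >= r_catheter)
        stop("geometry construction: sleeve collides with catheter outer wall ",
             "(r_outer + sleeve_gap + sleeve_thickness >= r_catheter)")
    }
    if (dims$concept == "monopole")
      stopifnot(monopole_exposed_length > 0,
                monopole_exposed_length < probe_length)
  })
  invisible(dims)
}

#' Tissue domain specification
#'
#' Axisymmetric tissue cylinder in which the probe is embedded. The probe
#' enters through the top face (z = 0) and z increases along the insertion
#' direction; the probe tip sits at z = `insertion`.
#'
#' @param tissue_height Height of the tissue cylinder in m (default 0.08).
#' @param tissue_radius Radius of the tissue cylinder in m (default 0.04).
#' @param insertion Depth of the probe tip below the entry face in m;
#'   defaults to the probe length (fully inserted probe).
#' @return An object of class `mwa_domain`.
#' @export
domain_spec <- function(tissue_height = 0.08, tissue_radius = 0.04,
                        insertion = NULL) {
  stopifnot(tissue_height > 0, tissue_radius > 0)
  structure(list(tissue_height = tissue_height, tissue_radius = tissue_radius,
                 insertion = insertion),
            class = "mwa_domain")
}

# One axis-aligned rectangle in the (r, z) half-plane.
.rect <- function(name, r0, r1, z0, z1) {
  if (r1 <= r0 || z1 <= z0)
    stop("geometry construction: degenerate rectangle for '", name, "'")
  list(name = name, r0 = r0, r1 = r1, z0 = z0, z1 = z1)
}

.rect_area <- function(rc) (rc$r1 - rc$r0) * (rc$z1 - rc$z0)

.rect_overlap <- function(a, b) {
  (a$r0 < b$r1 && b$r0 < a$r1 && a$z0 < b$z1 && b$z0 < a$z1)
}

.rect_polygon <- function(rc) {
  # closed, counter-clockwise in the (r, z) frame
  cbind(r = c(rc$r0, rc$r1, rc$r1, rc$r0, rc$r0),
        z = c(rc$z0, rc$z0, rc$z1, rc$z1, rc$z0))
}

#' Build the axisymmetric probe-in-tissue geometry
#'
#' Constructs the tagged (r, z) geometry of one probe concept embedded in the
#' tissue cylinder. Conductors (inner conductor, outer conductor pieces, the
#' shorting disc at the coax end, and the SSS sleeve) are excluded holes whose
#' surfaces carry the PEC tag. Material regions are `tissue`,
#' `coax_dielectric`, `catheter`, `slot_fill` and (SSS) `sleeve_gap_fill`.
#' Exterior boundaries are tagged `port` (coax input annulus at z = 0),
#' `outer_absorbing` (tissue outer faces), `pec` (conductor surfaces and the
#' probe shaft entry edge) and `axis` (r = 0 where exposed).
#'
#' @param concept One of [probe_concepts()].
#' @param dims A [default_dimensions()] object (possibly modified).
#' @param domain A [domain_spec()] object.
#' @return An object of class `mwa_geometry` with elements `regions` (list of
#'   named rectangles), `holes` (conductor rectangles), `boundaries`
#'   (data.frame of tagged segments) and the inputs.
#' @export
build_probe_geometry <- function(concept = "single_slot",
                                 dims = default_dimensions(concept),
                                 domain = domain_spec()) {
  concept <- .match_concept(concept)
  if (!identical(dims$concept, concept))
    stop("dims were built for concept '", dims$concept, "', not '", concept, "'")
  .validate_dimensions(dims)

  H <- domain$tissue_height
  R <- domain$tissue_radius
  L <- if (is.null(domain$insertion)) dims$probe_length else domain$insertion
  if (L > dims$probe_length)
    stop("insertion deeper than the probe is long")
  if (L + 2e-3 > H)
    stop("probe tip too close to the tissue bottom face")
  if (dims$r_catheter >= R)
    stop("catheter does not fit inside the tissue radius")

  ri <- dims$r_inner; rd <- dims$r_dielectric
  ro <- dims$r_outer; rc <- dims$r_catheter
  t_cap <- rc - ro                    # catheter wall thickness forms the tip cap
  z_cap <- L - t_cap                  # top of the tip cap
  t_short <- dims$short_thickness

  holes <- list()
  regions <- list()

  slot_z <- function(center) c(center - dims$slot_width / 2,
                               center + dims$slot_width / 2)

  if (concept %in% c("single_slot", "dual_slot", "sleeve_single_slot")) {
    z_short0 <- z_cap - t_short
    # slot z-intervals (slot centre measured from the probe tip)
    centers <- L - dims$slot_tip_offset
    if (concept == "dual_slot")
      centers <- c(centers - dims$slot_separation, centers)
    slots <- lapply(centers, slot_z)
    for (i in seq_along(slots)) {
      s <- slots[[i]]
      if (s[1] <= 0 || s[2] >= z_short0)
        stop("geometry construction: slot ", i,
             " extends outside the outer conductor")
    }
    if (length(slots) == 2 && slots[[1]][2] >= slots[[2]][1])
      stop("geometry construction: overlapping features: slot 1 and slot 2")

    holes$inner_conductor <- .rect("inner_conductor", 0, ri, 0, z_short0)
    holes$short <- .rect("short", 0, rd, z_short0, z_cap)
    # outer conductor pieces between slots
    oc_breaks <- c(0, unlist(slots), z_cap)
    k <- 1
    for (i in seq(1, length(oc_breaks) - 1, by = 2)) {
      holes[[paste0("outer_conductor_", k)]] <-
        .rect(paste0("outer_conductor_", k), rd, ro, oc_breaks[i], oc_breaks[i + 1])
      k <- k + 1
    }
    regions$coax_dielectric <- list(.rect("coax_dielectric", ri, rd, 0, z_short0))
    regions$slot_fill <- lapply(seq_along(slots), function(i)
      .rect("slot_fill", rd, ro, slots[[i]][1], slots[[i]][2]))

    cath <- list(.rect("catheter", 0, rc, z_cap, L))   # tip cap
    if (concept == "sleeve_single_slot") {
      sg0 <- ro + dims$sleeve_gap
      sg1 <- sg0 + dims$sleeve_thickness
      sl_z1 <- slots[[1]][1] - dims$sleeve_start_offset  # sleeve bottom edge
      sl_z0 <- sl_z1 - dims$sleeve_length
      if (sl_z0 <= 0)
        stop("geometry construction: sleeve extends above the entry plane")
      if (sl_z1 >= slots[[1]][1])
        stop("geometry construction: overlapping features: sleeve and slot")
      holes$sleeve <- .rect("sleeve", sg0, sg1, sl_z0, sl_z1)
      regions$sleeve_gap_fill <- list(.rect("sleeve_gap_fill", ro, sg0, sl_z0, sl_z1))
      cath <- c(cath, list(
        .rect("catheter", ro, rc, 0, sl_z0),
        .rect("catheter", ro, rc, sl_z1, z_cap),
        .rect("catheter", sg1, rc, sl_z0, sl_z1)))
    } else {
      cath <- c(cath, list(.rect("catheter", ro, rc, 0, z_cap)))
    }
    regions$catheter <- cath
  } else { # monopole
    z_oc <- z_cap - dims$monopole_exposed_length  # outer conductor end
    if (z_oc <= 0)
      stop("geometry construction: exposed monopole section longer than the probe")
    holes$inner_conductor <- .rect("inner_conductor", 0, ri, 0, z_cap)
    holes$outer_conductor_1 <- .rect("outer_conductor_1", rd, ro, 0, z_oc)
    regions$coax_dielectric <- list(.rect("coax_dielectric", ri, rd, 0, z_cap))
    regions$catheter <- list(
      .rect("catheter", 0, rc, z_cap, L),          # tip cap
      .rect("catheter", ro, rc, 0, z_cap),
      .rect("catheter", rd, ro, z_oc, z_cap))      # stripped band, polymer-filled
  }

  regions$tissue <- list(
    .rect("tissue", rc, R, 0, H),
    .rect("tissue", 0, rc, L, H))

  # pairwise non-overlap check across all regions and holes
  all_rects <- c(unlist(regions, recursive = FALSE), holes)
  nm <- vapply(all_rects, `[[`, "", "name")
  for (i in seq_along(all_rects)) {
    for (j in seq_len(i - 1L)) {
      if (.rect_overlap(all_rects[[i]], all_rects[[j]]))
        stop("geometry construction: overlapping features: '", nm[j],
             "' and '", nm[i], "'")
    }
  }

  boundaries <- rbind(
    data.frame(tag = "port", r0 = ri, r1 = rd, z0 = 0, z1 = 0),
    data.frame(tag = "pec", r0 = 0, r1 = ri, z0 = 0, z1 = 0),
    data.frame(tag = "pec", r0 = rd, r1 = ro, z0 = 0, z1 = 0),
    data.frame(tag = "pec", r0 = ro, r1 = rc, z0 = 0, z1 = 0),
    data.frame(tag = "outer_absorbing", r0 = rc, r1 = R, z0 = 0, z1 = 0),
    data.frame(tag = "outer_absorbing", r0 = R, r1 = R, z0 = 0, z1 = H),
    data.frame(tag = "outer_absorbing", r0 = 0, r1 = R, z0 = H, z1 = H),
    data.frame(tag = "axis", r0 = 0, r1 = 0, z0 = z_cap, z1 = H)
  )

  structure(list(concept = concept, dims = dims, domain = domain,
                 regions = regions, holes = holes, boundaries = boundaries,
                 probe_tip = L, cap_top = z_cap),
            class = "mwa_geometry")
}

#' Region polygons of a geometry
#'
#' Closed counter-clockwise polygons (columns `r`, `z`, in m) for every
#' rectangle of every material region.
#'
#' @param geometry An `mwa_geometry`.
#' @param holes Also include the conductor holes.
#' @return Named list of 5x2 matrices.
#' @export
geometry_polygons <- function(geometry, holes = FALSE) {
  rects <- unlist(geometry$regions, recursive = FALSE)
  if (holes) rects <- c(rects, geometry$holes)
  out <- lapply(rects, .rect_polygon)
  names(out) <- vapply(rects, `[[`, "", "name")
  out
}

#' Total area of the electromagnetic domain
#'
#' Half-plane (r, z) area of the meshed EM domain: the tissue cylinder
#' cross-section minus the conductor cross-sections.
#'
#' @param geometry An `mwa_geometry`.
#' @return Area in m^2.
#' @export
em_domain_area <- function(geometry) {
  dom <- geometry$domain
  full <- dom$tissue_radius * dom$tissue_height
  full - sum(vapply(geometry$holes, .rect_area, 0))
}

#' Export a geometry as structured text
#'
#' Writes a plain-text description (one `region <name>` block per rectangle,
#' followed by its vertices in m) for debugging and external checking.
#'
#' @param geometry An `mwa_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_geometry_text <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mwablate geometry: %s", geometry$concept), con)
  polys <- geometry_polygons(geometry, holes = TRUE)
  for (i in seq_along(polys)) {
    writeLines(sprintf("region %s", names(polys)[i]), con)
    p <- polys[[i]]
    writeLines(sprintf("  %.9g %.9g", p[, 1], p[, 2]), con)
  }
  bd <- geometry$boundaries
  for (i in seq_len(nrow(bd)))
    writeLines(sprintf("boundary %s  %.9g %.9g  %.9g %.9g",
                       bd$tag[i], bd$r0[i], bd$z0[i], bd$r1[i], bd$z1[i]), con)
  invisible(path)
}

#' @exportS3Method print mwa_geometry
print.mwa_geometry <- function(x, ...) {
  cat("mwablate geometry:", x$concept, "\n")
  cat(sprintf("  tissue cylinder: %.0f mm high, %.0f mm radius; tip at z = %.1f mm\n",
              x$domain$tissue_height * 1e3, x$domain$tissue_radius * 1e3,
              x$probe_tip * 1e3))
  nrect <- vapply(x$regions, length, 0L)
  cat("  regions:", paste(sprintf("%s (%d)", names(nrect), nrect), collapse = ", "), "\n")
  cat("  conductor holes:", paste(names(x$holes), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method print mwa_dimensions
print.mwa_dimensions <- function(x, ...) {
  cat("mwablate probe dimensions:", x$concept, "\n")
  for (nm in setdiff(names(x), "concept")) {
    v <- x[[nm]]
    if (is.na(v)) next
    cat(sprintf("  %-24s %8.3f mm\n", nm, v * 1e3))
  }
  invisible(x)
}
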