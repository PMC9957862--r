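test_that("four probe concepts with the documented default dimensions", {
  expect_identical(probe_concepts(),
                   c("monopole", "single_slot", "dual_slot",
                     "sleeve_single_slot"))
  d <- default_dimensions("single_slot")
  expect_equal(d$r_inner, 0.135e-3)
  expect_equal(d$r_dielectric, 0.335e-3)
  expect_equal(d$r_outer, 0.46e-3)
  expect_equal(d$r_catheter, 0.895e-3)
  expect_equal(d$slot_width, 1e-3)
  expect_equal(d$probe_length, 70e-3)
  expect_equal(d$slot_tip_offset, 5e-3)
  # concept-specific fields are NA where they do not apply
  expect_true(is.na(d$slot_separation))
  expect_true(is.na(d$monopole_exposed_length))
  expect_equal(default_dimensions("dual_slot")$slot_separation, 8e-3)
  expect_equal(default_dimensions("monopole")$monopole_exposed_length, 10e-3)
  expect_equal(default_dimensions("sleeve_single_slot")$sleeve_thickness,
               0.15e-3)
})

test_that("geometries are tagged, consistent, and non-overlapping", {
  for (cc in probe_concepts()) {
    geo <- build_probe_geometry(cc)
    expect_s3_class(geo, "mwa_geometry")
    expect_true(all(c("tissue", "coax_dielectric", "catheter") %in%
                      names(geo$regions)))
    expect_true("port" %in% geo$boundaries$tag)
    expect_true("outer_absorbing" %in% geo$boundaries$tag)
    # the port is exactly the dielectric annulus at z = 0
    p <- geo$boundaries[geo$boundaries$tag == "port", ]
    expect_equal(p$r0, geo$dims$r_inner)
    expect_equal(p$r1, geo$dims$r_dielectric)
    expect_equal(c(p$z0, p$z1), c(0, 0))
    # fully inserted probe: tip at probe_length
    expect_equal(geo$probe_tip, geo$dims$probe_length)
    # region + hole areas tile the tissue cylinder cross-section exactly
    rects <- c(unlist(geo$regions, recursive = FALSE), geo$holes)
    tiled <- sum(vapply(rects, function(rc)
      (rc$r1 - rc$r0) * (rc$z1 - rc$z0), 0))
    full <- geo$domain$tissue_radius * geo$domain$tissue_height
    expect_equal(tiled, full, tolerance = 1e-12)
    expect_equal(em_domain_area(geo),
                 full - sum(vapply(geo$holes, function(rc)
                   (rc$r1 - rc$r0) * (rc$z1 - rc$z0), 0)))
  }
  # slot count: one fill rectangle for SS/SSS, two for DS
  expect_length(build_probe_geometry("single_slot")$regions$slot_fill, 1)
  expect_length(build_probe_geometry("dual_slot")$regions$slot_fill, 2)
  expect_true(!is.null(build_probe_geometry("sleeve_single_slot")$holes$sleeve))
})

test_that("invalid feature placements are rejected with named errors", {
  d <- default_dimensions("dual_slot")
  d$slot_separation <- 0.5e-3               # slots overlap
  expect_error(build_probe_geometry("dual_slot", d), "overlapping features")

  d <- default_dimensions("sleeve_single_slot")
  d$sleeve_gap <- 1e-3                      # sleeve through the catheter wall
  expect_error(build_probe_geometry("sleeve_single_slot", d),
               "sleeve collides")

  d <- default_dimensions("single_slot")
  d$slot_tip_offset <- 69.9e-3              # slot off the top of the probe
  expect_error(build_probe_geometry("single_slot", d))

  expect_error(
    build_probe_geometry("single_slot",
                         domain = domain_spec(tissue_height = 0.06)),
    "too close to the tissue bottom")
  expect_error(
    build_probe_geometry("single_slot", default_dimensions("monopole")),
    "built for concept")
})

test_that("geometry polygons and text export round the same rectangles", {
  geo <- build_probe_geometry("single_slot")
  polys <- geometry_polygons(geo, holes = TRUE)
  expect_true(all(vapply(polys, nrow, 0L) == 5))      # closed rectangles
  expect_true(all(vapply(polys, function(p)
    all(p[1, ] == p[5, ]), TRUE)))
  path <- tempfile(fileext = ".txt")
  export_geometry_text(geo, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^region ", txt)), length(polys))
  expect_equal(sum(grepl("^boundary ", txt)), nrow(geo$boundaries))
})
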