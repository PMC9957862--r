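test_that("probe mesh is conforming, oriented, and region-exact", {
  geo <- build_probe_geometry("single_slot")
  ctl <- mesh_controls()
  mesh <- generate_mesh(geo, ctl)
  v <- mesh$vertices; tr <- mesh$triangles
  expect_equal(ncol(v), 2)
  expect_equal(ncol(tr), 3)

  # counter-clockwise orientation: strictly positive signed areas
  sa <- ((v[tr[, 2], 1] - v[tr[, 1], 1]) * (v[tr[, 3], 2] - v[tr[, 1], 2]) -
         (v[tr[, 3], 1] - v[tr[, 1], 1]) * (v[tr[, 2], 2] - v[tr[, 1], 2])) / 2
  expect_true(all(sa > 0))

  # conformity: every edge belongs to one or two triangles, and the
  # single-use edges are exactly the tagged boundary edges
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uses <- table(key)
  expect_true(all(uses %in% 1:2))
  bkey <- paste(pmin(mesh$boundary_edges$v1, mesh$boundary_edges$v2),
                pmax(mesh$boundary_edges$v1, mesh$boundary_edges$v2))
  expect_setequal(names(uses)[uses == 1], bkey)
  expect_setequal(unique(mesh$boundary_edges$tag),
                  c("port", "pec", "outer_absorbing", "axis"))

  # triangles tile each material region exactly (no leaked/lost area)
  reg <- mesh$region_names[mesh$region_id]
  for (nm in names(geo$regions)) {
    ga <- sum(vapply(geo$regions[[nm]], function(rc)
      (rc$r1 - rc$r0) * (rc$z1 - rc$z0), 0))
    expect_equal(sum(abs(sa)[reg == nm]), ga, tolerance = 1e-12)
  }

  # size control: element diameter at most h_fine inside the slot and at
  # most one wavelength / wavelength_points in the tissue
  emax <- pmax(
    sqrt(rowSums((v[tr[, 2], ] - v[tr[, 1], ])^2)),
    sqrt(rowSums((v[tr[, 3], ] - v[tr[, 2], ])^2)),
    sqrt(rowSums((v[tr[, 1], ] - v[tr[, 3], ])^2)))
  expect_lte(max(emax[reg == "slot_fill"]), ctl$h_fine)
  lam <- mwablate:::.tissue_wavelength(default_materials(), 2.45e9)
  expect_lte(max(emax[reg == "tissue"]), lam / ctl$wavelength_points)
})

test_that("meshing is deterministic and refinement adds elements", {
  geo <- build_probe_geometry("dual_slot")
  ctl <- mesh_controls(h_fine = 3e-4, h_far = 4e-3, wavelength_points = 5)
  m1 <- generate_mesh(geo, ctl)
  m2 <- generate_mesh(geo, ctl)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
  expect_identical(m1$region_id, m2$region_id)
  expect_identical(m1$boundary_edges, m2$boundary_edges)

  fine <- generate_mesh(geo, mesh_controls(h_fine = 1.5e-4, h_far = 2e-3,
                                           wavelength_points = 8))
  expect_gt(nrow(fine$triangles), nrow(m1$triangles))
})

test_that("all four concepts mesh and keep their special regions", {
  ctl <- mesh_controls(h_fine = 3e-4, h_far = 4e-3, wavelength_points = 5)
  for (cc in probe_concepts()) {
    mesh <- generate_mesh(build_probe_geometry(cc), ctl)
    reg <- unique(mesh$region_names[mesh$region_id])
    expect_true(all(c("tissue", "coax_dielectric", "catheter") %in% reg))
    if (cc != "monopole") expect_true("slot_fill" %in% reg)
    if (cc == "sleeve_single_slot") expect_true("sleeve_gap_fill" %in% reg)
  }
})

test_that("mesh interchange files round-trip", {
  geo <- coax_line_geometry()
  mesh <- generate_mesh(geo, mesh_controls(h_fine = 1e-4, h_far = 1e-3),
                        materials = NULL, frequency = NULL)
  path <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, path)
  back <- read_mesh_msh(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12)
  expect_identical(back$triangles, mesh$triangles)
  expect_identical(mesh$region_names[mesh$region_id],
                   back$region_names[back$region_id])
  expect_identical(back$boundary_edges$tag, mesh$boundary_edges$tag)
})
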