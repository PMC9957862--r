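test_that("sigmoid dielectric model: values, monotonicity, asymptotes", {
  co <- sigmoid_coefficients()
  # body temperature values of the default liver fit
  expect_equal(permittivity_at_temperature(37, co), 47.9, tolerance = 0.01)
  expect_equal(conductivity_at_temperature(37, co), 2.10, tolerance = 0.01)
  # strictly decreasing over a wide range
  Ts <- seq(-50, 300, by = 0.5)
  expect_true(all(diff(permittivity_at_temperature(Ts, co)) < 0))
  expect_true(all(diff(conductivity_at_temperature(Ts, co)) < 0))
  # asymptotes: alpha3 + 1 and beta3 at low T; 1 and 0 at high T
  expect_equal(permittivity_at_temperature(-1e4, co), co$alpha3 + 1)
  expect_equal(permittivity_at_temperature(1e4, co), 1)
  expect_equal(conductivity_at_temperature(-1e4, co), co$beta3)
  expect_equal(conductivity_at_temperature(1e4, co), 0)
  # half the span exactly at the sigmoid centres
  expect_equal(permittivity_at_temperature(co$alpha2, co), co$alpha3 / 2 + 1)
  expect_equal(conductivity_at_temperature(co$beta2, co), co$beta3 / 2)
  # overflow-safe for extreme arguments
  expect_true(is.finite(permittivity_at_temperature(1e6, co)))
  expect_error(permittivity_at_temperature(NaN, co))
})

test_that("material_field maps regions and honours the property mode", {
  run <- fx_probe_em()
  mesh <- run$mesh
  regions <- mesh$region_names[mesh$region_id]
  mats <- default_materials()
  pf <- material_field(mesh, 37, mats)
  expect_length(pf$eps_r, nrow(mesh$triangles))
  expect_equal(unique(pf$eps_r[regions == "catheter"]), 2.6)
  expect_equal(unique(pf$eps_r[regions == "coax_dielectric"]), 2.03)
  expect_equal(unique(pf$sigma[regions != "tissue"]), 0)
  expect_equal(unique(pf$eps_r[regions == "tissue"]),
               permittivity_at_temperature(37))

  # dynamic mode responds to temperature; constant mode stays at T_ref
  hot <- rep(90, nrow(mesh$vertices))
  pf_hot <- material_field(mesh, hot, mats)
  expect_lt(max(pf_hot$eps_r[regions == "tissue"]),
            min(pf$eps_r[regions == "tissue"]))
  mats_const <- default_materials(property_mode = "constant")
  pf_const <- material_field(mesh, hot, mats_const)
  expect_equal(pf_const$eps_r, pf$eps_r)
  expect_equal(pf_const$sigma, pf$sigma)

  expect_error(material_field(mesh, c(37, 37), mats), "dimension error")
})
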