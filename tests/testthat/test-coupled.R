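test_that("configuration validation", {
  expect_s3_class(simulation_config(), "mwa_config")
  expect_error(simulation_config(duration = 12, dt = 5),
               "integer multiple of dt")
  expect_error(simulation_config(sar_threshold = 0), "thresholds must be > 0")
  expect_error(simulation_config(temp_threshold = -5),
               "thresholds must be > 0")
  expect_error(simulation_config(concept = "helical"))
  # property_mode argument overrides the materials object
  cfg <- simulation_config(materials = default_materials(property_mode =
                                                           "dynamic"),
                           property_mode = "constant")
  expect_identical(cfg$materials$property_mode, "constant")
})

test_that("record layout: one row per step plus t = 0, fixed columns", {
  sim <- fx_coarse_run("dynamic")
  r <- sim$records
  expect_identical(names(r), c("t", "s11_db", "sar_area", "sar_circularity",
                               "temp_area", "temp_circularity", "T_max"))
  expect_equal(nrow(r), sim$config$duration / sim$config$dt + 1)
  expect_equal(r$t, seq(0, sim$config$duration, by = sim$config$dt))
  # t = 0: uniform body temperature, no 50 degC region yet
  expect_equal(r$T_max[1], 37)
  expect_equal(r$temp_area[1], 0)
  expect_true(is.na(r$temp_circularity[1]))
  # heating: monotone T_max and non-decreasing 50 degC area
  expect_true(all(diff(r$T_max) > 0))
  expect_true(all(diff(r$temp_area) >= 0))
  expect_true(all(r$sar_area > 0))
  expect_true(all(is.finite(r$s11_db)))
})

test_that("zero input power: no heating, no thresholded shapes", {
  sim <- run_simulation(fx_coarse_config(power = 0))
  r <- sim$records
  expect_equal(max(abs(r$T_max - 37)), 0, tolerance = 1e-9)
  expect_true(all(r$temp_area == 0))
  expect_true(all(r$sar_area == 0))
  expect_true(all(is.na(r$sar_circularity)))
})

test_that("constant-property mode keeps the EM problem step-invariant", {
  sim <- fx_coarse_run("constant")
  r <- sim$records
  expect_equal(diff(range(r$s11_db)), 0, tolerance = 1e-9)
  expect_equal(diff(range(r$sar_area)), 0, tolerance = 1e-9)
  expect_equal(diff(range(r$sar_circularity)), 0, tolerance = 1e-9)
  # the temperature still evolves
  expect_gt(r$T_max[nrow(r)], 50)

  # dynamic mode re-solves: S11 moves as the tissue heats
  dyn <- fx_coarse_run("dynamic")
  expect_gt(diff(range(dyn$records$s11_db)), 1e-4)
})

test_that("reruns of a fixed configuration are bit-identical", {
  sim1 <- run_simulation(fx_coarse_config())
  sim2 <- run_simulation(fx_coarse_config())
  expect_identical(sim1$records, sim2$records)
  # and match the memoized fixture run of the same configuration
  expect_identical(sim1$records, fx_coarse_run("dynamic")$records)
})

test_that("keep_shapes returns the final isocontour shapes", {
  sim <- run_simulation(fx_coarse_config(), keep_shapes = TRUE)
  expect_s3_class(sim$shapes$sar, "mwa_shape")
  expect_s3_class(sim$shapes$temperature, "mwa_shape")
  m <- shape_metrics(sim$shapes$sar)
  expect_equal(m$area, sim$records$sar_area[nrow(sim$records)])
})

test_that("stage failures carry step and stage context", {
  cfg <- fx_coarse_config()
  cfg$dims$r_inner <- -1      # corrupt after construction
  expect_error(run_simulation(cfg), "stage 'geometry'")
})
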