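test_that("insulated zero-source step leaves the temperature unchanged", {
  run <- fx_probe_em()
  st <- thermal_state(run$mesh, default_materials())
  st1 <- step_bioheat(st, rep(0, nrow(run$mesh$triangles)), 5)
  expect_lt(max(abs(st1$T - 37)), 1e-9)
  expect_equal(st1$time, 5)
})

test_that("uniform source raises the temperature by q dt / (rho C)", {
  run <- fx_probe_em()
  mats <- default_materials()
  st <- thermal_state(run$mesh, mats)
  q <- 5e5
  dt <- 2
  st1 <- step_bioheat(st, rep(q, nrow(run$mesh$triangles)), dt)
  rise <- q * dt / (mats$thermal$rho * mats$thermal$C)
  expect_equal(max(st1$dof), 37 + rise, tolerance = 1e-9)
  expect_equal(min(st1$dof), 37 + rise, tolerance = 1e-9)
})

test_that("each implicit step conserves energy to solver precision", {
  run <- fx_probe_em()
  st <- thermal_state(run$mesh, default_materials())
  # analytic revolved tissue 'volume moment' 2 pi int r dA for a unit source
  geo <- run$geo
  R <- geo$domain$tissue_radius; H <- geo$domain$tissue_height
  rc <- geo$dims$r_catheter; L <- geo$probe_tip
  vol <- 2 * pi * ((R^2 - rc^2) / 2 * H + rc^2 / 2 * (H - L))
  dt <- 5
  h0 <- heat_content(st)
  st1 <- step_bioheat(st, rep(1, nrow(run$mesh$triangles)), dt)
  expect_equal(heat_content(st1) - h0, dt * vol * 1, tolerance = 1e-7)
  # and with the real (non-uniform) loss field, against the quadrature power
  Qs <- run$sol$Qs
  st2 <- step_bioheat(st1, Qs, dt)
  reg <- run$mesh$region_names[run$mesh$region_id]
  expect_equal(heat_content(st2) - heat_content(st1),
               dt * run$sol$absorbed_power, tolerance = 1e-7)
  expect_true(all(Qs[reg != "tissue"] == 0))  # all loss power enters tissue
})

test_that("heating never cools below the initial temperature", {
  run <- fx_probe_em()
  st <- thermal_state(run$mesh, default_materials())
  for (i in 1:4) st <- step_bioheat(st, run$sol$Qs, 5)
  expect_gte(min(st$dof), 37 - 1e-6)
  expect_gt(max(st$dof), 38)  # the slot region actually heats
})

test_that("time stepping self-converges as dt is refined", {
  run <- fx_probe_em()
  Qs <- run$sol$Qs
  advance <- function(dt, t_end) {
    st <- thermal_state(run$mesh, default_materials())
    for (i in seq_len(round(t_end / dt))) st <- step_bioheat(st, Qs, dt)
    st$dof
  }
  ref <- advance(0.25, 10)
  err <- vapply(c(5, 2.5, 1.25), function(dt)
    max(abs(advance(dt, 10) - ref)), 0)
  expect_true(all(diff(err) < 0))              # first-order decay
  expect_lt(err[3] / max(abs(ref - 37)), 0.05) # small at the finest step
})

test_that("temperature evaluation and input validation", {
  run <- fx_probe_em()
  st <- step_bioheat(thermal_state(run$mesh, default_materials()),
                     run$sol$Qs, 5)
  geo <- run$geo
  # inside the probe (not part of the thermal domain): initial temperature
  # (2e-4, 0.02) lies in the coax dielectric, inside the probe
  expect_equal(evaluate_temperature(st, cbind(2e-4, 0.02)), 37)
  # outside the meshed domain: NA
  expect_true(is.na(evaluate_temperature(st, cbind(0.05, 0.05))))
  # near the slot: heated
  zslot <- geo$probe_tip - geo$dims$slot_tip_offset
  expect_gt(evaluate_temperature(st, cbind(1.2e-3, zslot)), 37.5)

  expect_error(step_bioheat(st, c(1, 2, 3), 5), "one value per mesh element")
  expect_error(step_bioheat(st, rep(NaN, nrow(run$mesh$triangles)), 5),
               "non-finite")
})
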