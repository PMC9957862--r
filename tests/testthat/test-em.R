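test_that("port source arithmetic: impedance, amplitude, incident field", {
  expect_equal(coax_wave_impedance(1), 376.730, tolerance = 1e-5)
  expect_equal(coax_wave_impedance(4), 376.730 / 2, tolerance = 1e-5)
  # closed form: A0 = sqrt(P Z / (pi ln(ro/ri)))
  expect_equal(incident_amplitude(1, pi, 1, exp(1)), 1)
  expect_equal(incident_amplitude(0, 50, 1e-4, 3e-4), 0)
  expect_equal(incident_amplitude(4, 50, 1e-4, 3e-4),
               2 * incident_amplitude(1, 50, 1e-4, 3e-4))
  expect_error(incident_amplitude(1, 50, 3e-4, 1e-4), "r_o must exceed")

  src <- make_source(power = 30)
  rr <- seq(src$r_i, src$r_o, length.out = 7)
  expect_equal(Mod(incident_field(src, rr)), src$A0 / rr)
  expect_error(incident_field(src, 1e-5), "outside the port annulus")
  # the TEM amplitude reproduces the input power through the Poynting
  # integral P = pi ln(ro/ri) A0^2 / Z
  expect_equal(pi * log(src$r_o / src$r_i) * src$A0^2 / src$Z, 30)
})

test_that("reflection coefficient projection on trivial port fields", {
  src <- make_source()
  r <- seq(src$r_i, src$r_o, length.out = 201)
  E_inc <- incident_field(src, r)
  expect_equal(reflection_coefficient(E_inc, E_inc, r), 0 + 0i)
  expect_equal(reflection_coefficient(0 * E_inc, E_inc, r), -1 + 0i)
  expect_equal(reflection_coefficient(2 * E_inc, E_inc, r), 1 + 0i)
  expect_error(reflection_coefficient(E_inc, 0 * E_inc, r),
               "zero incident energy")

  expect_equal(s11_db(0.5 + 0i), 20 * log10(0.5))
  expect_equal(s11_db(1e-12 + 0i), -160)   # floor, no -Inf
})

test_that("matched coax oracle: near-zero reflection, analytic 1/r field", {
  cx <- fx_coax("absorbing")
  sol <- cx$sol
  expect_lte(Mod(sol$gamma), 0.05)
  expect_equal(sol$absorbed_power, 0)          # lossless fill
  expect_lte(sol$residual, 1e-8)

  src <- cx$src
  rr <- seq(src$r_i * 1.05, src$r_o * 0.95, length.out = 21)
  pts <- cbind(rr, 0.01)
  ev <- evaluate_em_field(sol, pts)
  expect_equal(Mod(ev$E_r), src$A0 / rr, tolerance = 0.02)
  expect_lt(max(Mod(ev$E_z)) / max(Mod(ev$E_r)), 0.02)
  # outside the meshed domain: NA
  out <- evaluate_em_field(sol, cbind(0.05, 0.05))
  expect_true(is.na(out$Qs))
})

test_that("shorted lossless coax: total reflection", {
  sol <- fx_coax("short")$sol
  expect_equal(Mod(sol$gamma), 1, tolerance = 0.01)
  expect_equal(sol$absorbed_power, 0)
})

test_that("lossy shorted coax is passive and closes the energy balance", {
  # lossless oracles cannot detect a time-convention sign error (the
  # conjugate solution has the same |Gamma|); a lossy line can: any sign
  # mixup turns absorption into gain and pushes |Gamma| above 1.
  cx <- fx_coax("short", sigma = 2)
  sol <- cx$sol
  expect_lt(Mod(sol$gamma), 1)
  expect_length(sol$warnings, 0)
  expect_true(all(sol$Qs >= 0))
  expect_gt(sol$absorbed_power, 0)
  Pin <- sol$source$power
  expect_equal(sol$absorbed_power, (1 - Mod(sol$gamma)^2) * Pin,
               tolerance = 0.01)
})

test_that("field and power scale with the source amplitude", {
  cx <- fx_coax("short", sigma = 2)
  src4 <- make_source(power = 4 * cx$src$power)
  sol1 <- cx$sol
  sol4 <- solve_em(cx$mesh, cx$props, src4)
  expect_equal(sol4$gamma, sol1$gamma, tolerance = 1e-9)
  expect_equal(sol4$absorbed_power, 4 * sol1$absorbed_power,
               tolerance = 1e-9)
  expect_equal(sol4$Qs, 4 * sol1$Qs, tolerance = 1e-9)
})

test_that("probe solve: power balance, positivity, loss localisation", {
  run <- fx_probe_em()
  sol <- run$sol
  expect_lt(Mod(sol$gamma), 1)
  expect_lt(sol$s11_db, 0)
  expect_lte(sol$residual, 1e-8)
  # power balance: (1 - |Gamma|^2) P_in = revolved integral of Qs, within 5%
  Pnet <- (1 - Mod(sol$gamma)^2) * sol$source$power
  expect_equal(sol$absorbed_power, Pnet, tolerance = 0.05)
  # losses only where sigma > 0 (the tissue)
  expect_true(all(sol$Qs >= 0))
  reg <- run$mesh$region_names[run$mesh$region_id]
  expect_true(all(sol$Qs[reg != "tissue"] == 0))
  expect_gt(max(sol$Qs[reg == "tissue"]), 0)

  # loss-density rescaling matches a direct recompute
  sig2 <- run$props$sigma * 2
  expect_equal(compute_loss_density(sol, sig2), 2 * sol$Qs, tolerance = 1e-12)
})

test_that("solver input validation", {
  run <- fx_probe_em()
  bad <- run$props
  bad$eps_r <- bad$eps_r[-1]
  expect_error(solve_em(run$mesh, bad, run$src), "props/mesh mismatch")
})
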