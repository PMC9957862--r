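# Shared fixtures, built lazily on first use and memoized for the whole
# test run (meshes and EM solves are the expensive parts).
.fx_store <- new.env(parent = emptyenv())

fx <- function(name, make) {
  if (is.null(.fx_store[[name]])) .fx_store[[name]] <- make()
  .fx_store[[name]]
}

# Coax-line fixture: mesh + uniform props + source, at given termination
# and (optionally) a uniform dielectric conductivity.
fx_coax <- function(termination, sigma = 0, len = 0.02) {
  key <- sprintf("coax_%s_%g_%g", termination, sigma, len)
  fx(key, function() {
    geo <- coax_line_geometry(len = len, termination = termination)
    mesh <- generate_mesh(geo, mesh_controls(h_fine = 5e-5, h_far = 4e-4),
                          materials = NULL, frequency = NULL)
    props <- material_field(mesh, 37)
    props$sigma[] <- sigma
    src <- make_source()
    list(geo = geo, mesh = mesh, props = props, src = src,
         sol = solve_em(mesh, props, src))
  })
}

# Coarse single-slot probe configuration: fast (~1 s per EM solve) but a
# real end-to-end problem; used by the coupled/property tests.
fx_coarse_config <- function(...) {
  simulation_config("single_slot",
                    controls = mesh_controls(h_fine = 2.5e-4, h_far = 4e-3,
                                             wavelength_points = 6),
                    duration = 10, dt = 5, raster = 4e-4, ...)
}

fx_coarse_run <- function(mode = "dynamic") {
  fx(paste0("coarse_run_", mode), function()
    run_simulation(fx_coarse_config(property_mode = mode)))
}

# Coarse single-slot t = 0 EM solution (shared by em/bioheat tests).
fx_probe_em <- function() {
  fx("probe_em", function() {
    cfg <- fx_coarse_config()
    geo <- build_probe_geometry(cfg$concept, cfg$dims, cfg$domain)
    mesh <- generate_mesh(geo, cfg$controls, cfg$materials, cfg$frequency)
    props <- material_field(mesh, 37, cfg$materials)
    src <- make_source(frequency = cfg$frequency, power = cfg$power,
                       r_i = cfg$dims$r_inner, r_o = cfg$dims$r_dielectric,
                       eps_dielectric = cfg$materials$static$coax_dielectric$eps_r)
    list(geo = geo, mesh = mesh, props = props, src = src,
         sol = solve_em(mesh, props, src))
  })
}
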