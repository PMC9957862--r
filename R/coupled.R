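# Weakly coupled electromagnetic-thermal ablation simulation.
#
# Loop order per step (weak coupling, no inner iteration): take the loss
# density from the current EM solution, advance the temperature by one
# implicit step, update the tissue dielectric properties at the new
# temperature (dynamic mode) or keep the reference values (constant mode),
# re-solve the EM problem, and record. The t = 0 record is the first EM
# solve at uniform body temperature before any heating, so "initial"
# quantities map to record 1.

#' Simulation configuration
#'
#' Bundles everything a coupled run needs, with the standard defaults:
#' 2.45 GHz, 30 W input power, 300 s ablation in 5 s implicit steps,
#' SAR isocontour threshold 1 kW/m^3, temperature isocontour 50 degC.
#'
#' @param concept Probe concept, one of [probe_concepts()].
#' @param dims Probe dimensions ([default_dimensions()] of `concept` if
#'   omitted).
#' @param domain Tissue domain ([domain_spec()]).
#' @param controls Mesh controls ([mesh_controls()]).
#' @param materials Materials ([default_materials()]); its property mode is
#'   overridden by `property_mode`.
#' @param frequency Operating frequency in Hz.
#' @param power Input power in W.
#' @param duration Total ablation time in s; must be an integer multiple of
#'   `dt`.
#' @param dt Time step in s.
#' @param sar_threshold SAR isocontour threshold in W/m^3 (> 0).
#' @param temp_threshold Temperature isocontour threshold in degC (> 0).
#' @param property_mode `"dynamic"` (tissue dielectrics follow temperature)
#'   or `"constant"` (frozen at the reference temperature).
#' @param raster Shape-extraction raster spacing in m.
#' @return An object of class `mwa_config`.
#' @export
simulation_config <- function(concept = "single_slot",
                              dims = NULL,
                              domain = domain_spec(),
                              controls = mesh_controls(),
                              materials = default_materials(),
                              frequency = 2.45e9, power = 30,
                              duration = 300, dt = 5,
                              sar_threshold = 1000, temp_threshold = 50,
                              property_mode = c("dynamic", "constant"),
                              raster = 2e-4) {
  concept <- match.arg(concept, probe_concepts())
  property_mode <- match.arg(property_mode)
  if (is.null(dims)) dims <- default_dimensions(concept)
  stopifnot(frequency > 0, power >= 0, duration > 0, dt > 0)
  if (sar_threshold <= 0 || temp_threshold <= 0)
    stop("config error: thresholds must be > 0 (sar_threshold = ",
         sar_threshold, ", temp_threshold = ", temp_threshold, ")")
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-9)
    stop("config error: duration (", duration,
         " s) must be an integer multiple of dt (", dt, " s)")
  materials$property_mode <- property_mode
  structure(list(concept = concept, dims = dims, domain = domain,
                 controls = controls, materials = materials,
                 frequency = frequency, power = power,
                 duration = duration, dt = dt,
                 sar_threshold = sar_threshold,
                 temp_threshold = temp_threshold,
                 property_mode = property_mode, raster = raster),
            class = "mwa_config")
}

# Run one stage with step/stage context added to any error.
.stage <- function(step, stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("simulation aborted at step ", step, ", stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

# Shape metrics of field_fun at threshold: area 0 / circularity NA when the
# thresholded region is empty.
.shape_record <- function(field_fun, threshold, geometry, raster) {
  sh <- extract_threshold_shape(field_fun, threshold, geometry, raster)
  if (sh$empty)
    return(list(area = 0, circularity = NA_real_, shape = sh))
  m <- shape_metrics(sh)
  list(area = m$area, circularity = m$circularity, shape = sh)
}

#' Run the coupled ablation simulation
#'
#' Executes the full weakly coupled loop for `config` and records, at t = 0
#' and after every time step: S11 (dB), the SAR isocontour area and
#' circularity, the temperature isocontour area and circularity, and the
#' maximum tissue temperature. The run is deterministic: re-running the same
#' configuration bit-reproduces the time series.
#'
#' @param config An [simulation_config()] object.
#' @param keep_shapes Keep the extracted shapes of the final record in the
#'   result (for export/plotting).
#' @param progress Print one line per step (step index, S11, T_max).
#' @return An object of class `mwa_simulation`: `records` (data frame with
#'   columns `t`, `s11_db`, `sar_area`, `sar_circularity`, `temp_area`,
#'   `temp_circularity`, `T_max`), `config`, `geometry`, `mesh`, the final
#'   `em` solution and thermal `state`, and (optionally) final shapes.
#' @export
run_simulation <- function(config, keep_shapes = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "mwa_config"))
  geo <- .stage(0, "geometry",
                build_probe_geometry(config$concept, config$dims,
                                     config$domain))
  mesh <- .stage(0, "meshing",
                 generate_mesh(geo, config$controls, config$materials,
                               config$frequency))
  eps_d <- config$materials$static$coax_dielectric$eps_r
  src <- make_source(frequency = config$frequency, power = config$power,
                     r_i = config$dims$r_inner,
                     r_o = config$dims$r_dielectric,
                     eps_dielectric = eps_d)
  state <- thermal_state(mesh, config$materials)
  props <- .stage(0, "materials", material_field(mesh, state$T,
                                                 config$materials))
  sol <- .stage(0, "em_solve", solve_em(mesh, props, src))

  nsteps <- as.integer(round(config$duration / config$dt))
  n <- nsteps + 1L
  rec <- data.frame(t = numeric(n), s11_db = numeric(n),
                    sar_area = numeric(n), sar_circularity = numeric(n),
                    temp_area = numeric(n), temp_circularity = numeric(n),
                    T_max = numeric(n))
  shapes <- NULL
  record <- function(i, t) {
    sar <- .shape_record(function(p) evaluate_em_field(sol, p)$Qs,
                         config$sar_threshold, geo, config$raster)
    tmp <- .shape_record(function(p) evaluate_temperature(state, p),
                         config$temp_threshold, geo, config$raster)
    rec[i, ] <<- list(t, sol$s11_db, sar$area, sar$circularity,
                      tmp$area, tmp$circularity, max(state$dof))
    if (keep_shapes && i == n)
      shapes <<- list(sar = sar$shape, temperature = tmp$shape)
    if (progress)
      cat(sprintf("step %3d/%d  t = %5.0f s  S11 = %7.2f dB  Tmax = %6.1f degC\n",
                  i - 1L, nsteps, t, sol$s11_db, max(state$dof)))
  }
  .stage(0, "record", record(1L, 0))

  for (k in seq_len(nsteps)) {
    Qs <- sol$Qs
    state <- .stage(k, "thermal_step", step_bioheat(state, Qs, config$dt))
    if (config$property_mode == "dynamic") {
      props <- .stage(k, "property_update",
                      material_field(mesh, state$T, config$materials))
      sol <- .stage(k, "em_solve", solve_em(mesh, props, src))
    }
    # constant mode: frozen coefficients leave the EM problem identical, so
    # the t = 0 solution is reused verbatim
    .stage(k, "record", record(k + 1L, k * config$dt))
  }
  structure(list(records = rec, config = config, geometry = geo,
                 mesh = mesh, em = sol, state = state, shapes = shapes),
            class = "mwa_simulation")
}

#' @exportS3Method print mwa_simulation
print.mwa_simulation <- function(x, ...) {
  r <- x$records
  n <- nrow(r)
  cat(sprintf("mwablate simulation: %s, %g W, %g s (%d records, %s properties)\n",
              x$config$concept, x$config$power, x$config$duration, n,
              x$config$property_mode))
  cat(sprintf("  S11: %.2f dB (t = 0) -> %.2f dB (end);  T_max: %.1f degC\n",
              r$s11_db[1], r$s11_db[n], r$T_max[n]))
  cat(sprintf("  50 degC-type area: %.3g m^2 (end);  SAR area: %.3g m^2 (t = 0)\n",
              r$temp_area[n], r$sar_area[1]))
  invisible(x)
}
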