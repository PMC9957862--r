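# Configuration files, output writing, and the run manifest.

# Known configuration keys (nested) for validation.
.config_keys <- list(
  top = c("concept", "dims", "domain", "controls", "materials",
          "frequency", "power", "duration", "dt", "sar_threshold",
          "temp_threshold", "property_mode", "raster"),
  dims = c("r_inner", "r_dielectric", "r_outer", "r_catheter",
           "slot_width", "sleeve_thickness", "probe_length",
           "slot_tip_offset", "slot_separation", "sleeve_gap",
           "sleeve_start_offset", "sleeve_length",
           "monopole_exposed_length", "short_thickness"),
  domain = c("tissue_height", "tissue_radius", "insertion"),
  controls = c("h_fine", "h_far", "grading", "wavelength_points"),
  materials = c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
                "eps_dielectric", "sigma_dielectric", "eps_catheter",
                "sigma_catheter", "rho", "C", "k_l", "T_ref")
)

.check_keys <- function(given, section) {
  known <- .config_keys[[section]]
  bad <- setdiff(names(given), known)
  if (length(bad))
    stop("config error: unknown key", if (length(bad) > 1) "s" else "",
         " in '", section, "': ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Load a simulation configuration file
#'
#' Reads a structured-text (YAML) configuration, validates every key,
#' applies the documented defaults for anything omitted, and returns the
#' fully resolved [simulation_config()]. An empty file yields the full
#' default configuration (single-slot probe, 2.45 GHz, 30 W, 300 s, 5 s
#' steps). Unknown keys are rejected with an error naming the key.
#'
#' @param path Path to the configuration file.
#' @return An `mwa_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config error: top level must be a mapping")
  .check_keys(cfg, "top")
  for (sec in c("dims", "domain", "controls", "materials"))
    if (!is.null(cfg[[sec]])) .check_keys(cfg[[sec]], sec)

  concept <- cfg$concept %||% "single_slot"
  concept <- match.arg(concept, probe_concepts())
  dims <- default_dimensions(concept)
  if (!is.null(cfg$dims)) dims[names(cfg$dims)] <- cfg$dims
  dom_args <- cfg$domain %||% list()
  domain <- do.call(domain_spec, dom_args)
  controls <- do.call(mesh_controls, cfg$controls %||% list())
  m <- cfg$materials %||% list()
  sg_names <- c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3")
  sigmoid <- do.call(sigmoid_coefficients, m[intersect(names(m), sg_names)])
  mat_args <- m[setdiff(names(m), sg_names)]
  mat_args$sigmoid <- sigmoid
  materials <- do.call(default_materials, mat_args)

  simulation_config(
    concept = concept, dims = dims, domain = domain, controls = controls,
    materials = materials,
    frequency = cfg$frequency %||% 2.45e9,
    power = cfg$power %||% 30,
    duration = cfg$duration %||% 300,
    dt = cfg$dt %||% 5,
    sar_threshold = cfg$sar_threshold %||% 1000,
    temp_threshold = cfg$temp_threshold %||% 50,
    property_mode = cfg$property_mode %||% "dynamic",
    raster = cfg$raster %||% 2e-4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the run manifest
#'
#' Serialises the fully resolved configuration (every default expanded),
#' the material coefficient sets, mesh statistics, and the package version
#' with a timestamp — enough to bit-reproduce the run. Intended to be
#' written before solving begins.
#'
#' @param config An `mwa_config`.
#' @param path Output path (YAML).
#' @param mesh Optional `mwa_mesh` for mesh statistics.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, mesh = NULL) {
  num <- function(x) lapply(x, function(v)
    if (is.numeric(v) || is.character(v)) v else NULL)
  man <- list(
    package = "mwablate",
    version = as.character(utils::packageVersion("mwablate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    concept = config$concept,
    frequency = config$frequency, power = config$power,
    duration = config$duration, dt = config$dt,
    sar_threshold = config$sar_threshold,
    temp_threshold = config$temp_threshold,
    property_mode = config$property_mode,
    raster = config$raster,
    dims = config$dims[!is.na(unlist(config$dims))],
    domain = list(tissue_height = config$domain$tissue_height,
                  tissue_radius = config$domain$tissue_radius),
    controls = unclass(config$controls),
    materials = c(unclass(config$materials$sigmoid),
                  config$materials$thermal,
                  list(T_ref = config$materials$T_ref),
                  lapply(config$materials$static, unlist)))
  if (!is.null(mesh))
    man$mesh <- list(vertices = nrow(mesh$vertices),
                     triangles = nrow(mesh$triangles),
                     regions = as.list(table(
                       mesh$region_names[mesh$region_id])))
  yaml::write_yaml(man, path)
  invisible(path)
}

# Fixed documented column order of the time series.
.ts_columns <- c("t", "s11_db", "sar_area", "sar_circularity",
                 "temp_area", "temp_circularity", "T_max")

#' Write the simulation time series
#'
#' Comma-delimited table, one row per record, fixed column order
#' `t, s11_db, sar_area, sar_circularity, temp_area, temp_circularity,
#' T_max`, full double precision (round-trips losslessly through
#' [read_timeseries()]).
#'
#' @param records Data frame of records (from `run_simulation(...)$records`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) < 1)
    stop("write_timeseries: need at least one record")
  if (!all(.ts_columns %in% names(records)))
    stop("write_timeseries: records missing columns: ",
         paste(setdiff(.ts_columns, names(records)), collapse = ", "))
  df <- records[, .ts_columns]
  fmt <- as.data.frame(lapply(df, function(col) sprintf("%.17g", col)),
                       stringsAsFactors = FALSE)
  names(fmt) <- .ts_columns
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path File path.
#' @return Data frame with the documented columns.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  if (!identical(names(df), .ts_columns))
    stop("read_timeseries: unexpected columns in ", path)
  df
}

#' Write field snapshots in legacy VTK format
#'
#' ASCII legacy VTK unstructured grid of the (r, z) mesh with named
#' per-vertex (`point_data`) and per-element (`cell_data`) scalar arrays,
#' for standard visualization tools.
#'
#' @param mesh An `mwa_mesh`.
#' @param path Output `.vtk` path.
#' @param point_data Named list of numeric vectors (one per vertex).
#' @param cell_data Named list of numeric vectors (one per triangle).
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(mesh, path, point_data = list(),
                            cell_data = list()) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("mwablate field snapshot")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", nv, " double")
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]),
             con)
  wl("CELLS ", nt, " ", 4 * nt)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  wl("CELL_TYPES ", nt)
  writeLines(rep("5", nt), con)
  if (length(point_data)) {
    wl("POINT_DATA ", nv)
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == nv)
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA ", nt)
    for (nm in names(cell_data)) {
      stopifnot(length(cell_data[[nm]]) == nt)
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Run and collect all four probe concepts
#'
#' Convenience comparison driver: runs the same configuration for each
#' concept and returns the combined time series with a `concept` column.
#'
#' @param ... Arguments passed to [simulation_config()] (all but `concept`).
#' @param concepts Concepts to run (default all four).
#' @param progress Print per-step progress lines.
#' @return Data frame: `concept` plus the documented time-series columns.
#' @export
run_all_concepts <- function(..., concepts = probe_concepts(),
                             progress = FALSE) {
  out <- lapply(concepts, function(cc) {
    sim <- run_simulation(simulation_config(concept = cc, ...),
                          progress = progress)
    cbind(concept = cc, sim$records)
  })
  do.call(rbind, out)
}
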