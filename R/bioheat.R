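# Transient bioheat solver.
#
# The temperature field obeys rho C dT/dt = div(k grad T) + Qs on the
# tissue region only (the probe interior is excluded; its boundary with the
# tissue, like the outer domain boundary, is treated as thermally insulated,
# i.e. the natural zero-flux condition). Quadratic elements share the EM
# mesh; time stepping is backward Euler, unconditionally stable, with the
# system matrix factored once per step size (sparse Cholesky) and reused
# for every step.

# Thermal assembly on the tissue subdomain, cached on the mesh: reduced dof
# numbering over tissue elements, sparse mass and stiffness (axisymmetric
# weight r), per-element load vectors, and a factor store keyed by dt.
.thermal_cache <- function(mesh) {
  if (!is.null(mesh$cache$thermal)) return(mesh$cache$thermal)
  fem <- .fem_cache(mesh)
  tis <- which(mesh$region_names[mesh$region_id] == "tissue")
  if (!length(tis)) stop("mesh has no tissue region")
  dm <- fem$dofs$dofmap[tis, , drop = FALSE]
  gdofs <- sort(unique(as.vector(dm)))
  red <- integer(fem$dofs$ndof)
  red[gdofs] <- seq_along(gdofs)
  n <- length(gdofs)
  ii <- red[as.vector(fem$elem$ii[tis, , drop = FALSE])]
  jj <- red[as.vector(fem$elem$jj[tis, , drop = FALSE])]
  K <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = as.vector(fem$elem$Kth[tis, , drop = FALSE]),
                            dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = as.vector(fem$elem$M[tis, , drop = FALSE]),
                            dims = c(n, n))
  out <- list(tissue_elems = tis, gdofs = gdofs, red = red, n = n,
              K = K, M = M,
              load = fem$elem$load[tis, , drop = FALSE],
              load_dof = matrix(red[as.vector(dm)], nrow(dm), 6),
              factors = new.env(parent = emptyenv()))
  mesh$cache$thermal <- out
  out
}

#' Initial thermal state
#'
#' Creates the transient temperature state on the tissue region of a mesh,
#' at a uniform starting temperature.
#'
#' @param mesh An `mwa_mesh` from [generate_mesh()].
#' @param materials An [default_materials()] object (thermal constants).
#' @param T0 Initial temperature in degC (default 37, body temperature).
#' @return An object of class `mwa_thermal_state`: `T` (temperature at the
#'   mesh vertices; non-tissue vertices stay at `T0`), `time` (elapsed
#'   seconds) and internal dof values.
#' @export
thermal_state <- function(mesh, materials = default_materials(), T0 = 37) {
  th <- .thermal_cache(mesh)
  fem <- .fem_cache(mesh)
  state <- structure(list(
    dof = rep(as.numeric(T0), th$n),
    T = rep(as.numeric(T0), nrow(mesh$vertices)),
    time = 0, T0 = as.numeric(T0),
    mesh = mesh, materials = materials), class = "mwa_thermal_state")
  state
}

#' Advance the bioheat equation by one time step
#'
#' One backward-Euler step of `rho C dT/dt = div(k grad T) + Qs` on the
#' tissue region with insulated boundaries: solves
#' `(rho C M + dt k K) T_new = rho C M T_old + dt Q`. The sparse Cholesky
#' factor is computed on first use for a given `dt` and reused afterwards,
#' so repeated fixed-step calls cost one triangular solve each. The scheme
#' conserves energy exactly: the revolved heat content rises by
#' `dt * integral(Qs dV)` every step.
#'
#' @param state An [thermal_state()] object.
#' @param Qs Per-element loss density (W/m^3) over the whole mesh, e.g.
#'   `solve_em(...)$Qs`; only tissue elements contribute.
#' @param dt Time step in s.
#' @return The updated `mwa_thermal_state`.
#' @export
step_bioheat <- function(state, Qs, dt) {
  mesh <- state$mesh
  th <- .thermal_cache(mesh)
  if (length(Qs) != nrow(mesh$triangles))
    stop("step_bioheat: Qs must have one value per mesh element")
  if (!all(is.finite(Qs))) stop("step_bioheat: non-finite loss density")
  stopifnot(dt > 0)
  tc <- state$materials$thermal
  rhoC <- tc$rho * tc$C
  key <- sprintf("dt_%.17g", dt)
  F <- th$factors[[key]]
  if (is.null(F)) {
    A <- rhoC * th$M + dt * tc$k_l * th$K
    F <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
    th$factors[[key]] <- F
  }
  # load: dt * integral(Qs N_i r) per tissue element (Qs element-constant)
  q <- th$load * Qs[th$tissue_elems]
  b <- rhoC * as.vector(th$M %*% state$dof)
  bq <- rowsum(as.vector(q), as.vector(th$load_dof))
  idx <- as.integer(rownames(bq))
  b[idx] <- b[idx] + dt * bq[, 1]
  state$dof <- as.vector(Matrix::solve(F, b, system = "A"))
  # vertex temperatures for coupling/output (tissue vertices only)
  fem <- .fem_cache(mesh)
  nv <- nrow(mesh$vertices)
  vred <- th$red[fem$dofs$newid[seq_len(nv)]]
  upd <- vred > 0
  state$T[upd] <- state$dof[vred[upd]]
  state$time <- state$time + dt
  state
}

#' Evaluate the temperature field at points
#'
#' Quadratic interpolation of the current temperature at arbitrary (r, z)
#' points. Points outside the mesh give NA; points inside the probe (outside
#' the tissue region) return the initial temperature, since the probe
#' interior is not part of the thermal domain.
#'
#' @param state An [thermal_state()] object.
#' @param pts n x 2 matrix of (r, z) points in m.
#' @return Numeric vector of temperatures in degC.
#' @export
evaluate_temperature <- function(state, pts) {
  mesh <- state$mesh
  th <- .thermal_cache(mesh)
  fem <- .fem_cache(mesh)
  full <- rep(state$T0, fem$dofs$ndof)
  full[th$gdofs] <- state$dof
  Re(.p2_eval(mesh, fem$dofs, complex(real = full), pts)$value)
}

#' Revolved heat content of the tissue
#'
#' `2 pi rho C integral(T r dr dz)` over the tissue region, in J. Useful for
#' energy-balance checks: with insulated boundaries each backward-Euler step
#' raises it by exactly `dt` times the absorbed power.
#'
#' @param state An [thermal_state()] object.
#' @return Heat content in J (relative to 0 degC).
#' @export
heat_content <- function(state) {
  th <- .thermal_cache(state$mesh)
  tc <- state$materials$thermal
  2 * pi * tc$rho * tc$C * sum(state$dof * as.vector(th$M %*% rep(1, th$n)))
}

#' @exportS3Method print mwa_thermal_state
print.mwa_thermal_state <- function(x, ...) {
  th <- .thermal_cache(x$mesh)
  cat(sprintf("mwablate thermal state: t = %.1f s, T in [%.2f, %.2f] degC (%d tissue dofs)\n",
              x$time, min(x$dof), max(x$dof), th$n))
  invisible(x)
}
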