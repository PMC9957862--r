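# Axisymmetric frequency-domain electromagnetic solver.
#
# The coax feeds a rotationally symmetric TM field (E_r, E_z, H_phi). Instead
# of the meridian vector E field, the solver discretises the scalar
# w = r * H_phi with quadratic nodal elements. In terms of w the curl-curl
# equation for H_phi becomes
#
#   div[(1/eps~) grad(w) / r] + k0^2 w / r = 0,
#
# eps~ = eps_r - j sigma/(w eps0); the weak form carries the weight 1/r in
# both stiffness and mass. This choice is deliberate: the coax TEM mode
# (H_phi ~ 1/r) is w = const, exactly representable in the element space,
# so the guided feed propagates without the severe radial-resolution
# requirement the plain H_phi unknown would have. The electric field follows
# from Ampere's law, E = (curl H)/(j w eps0 eps~): E_r = -w_z/(j w eps0
# eps~ r), E_z = +w_r/(j w eps0 eps~ r). PEC surfaces (tangential E = 0)
# are the natural boundary condition, so conductors are simply excluded
# from the mesh; the coax port and the first-order absorbing truncation
# enter as Robin terms through the local TEM wave impedance; the symmetry
# axis carries the essential condition w = 0.

#' Coax TEM wave impedance
#'
#' Plane-wave impedance of the (lossless) coax dielectric,
#' `sqrt(mu0/eps0)/sqrt(eps_r)`, in Ohm.
#'
#' @param eps_r Relative permittivity of the dielectric.
#' @return Impedance in Ohm.
#' @export
coax_wave_impedance <- function(eps_r = 2.03) {
  stopifnot(eps_r >= 1)
  sqrt(.mu0 / .eps0) / sqrt(eps_r)
}

#' Incident TEM amplitude from input power
#'
#' Inverts the Poynting power integral of the coax TEM mode: for input power
#' `P`, dielectric wave impedance `Z` and annulus radii `r_i < r_o`, the peak
#' radial field amplitude is `A0 = sqrt(P Z / (pi ln(r_o/r_i)))` (in V; the
#' incident field is `A0/r` V/m across the annulus).
#'
#' @param power Input power in W.
#' @param Z Wave impedance of the coax dielectric in Ohm.
#' @param r_i,r_o Inner/outer radii of the dielectric annulus in m.
#' @return Amplitude A0 in V.
#' @export
incident_amplitude <- function(power, Z, r_i, r_o) {
  if (r_o <= r_i) stop("incident_amplitude: r_o must exceed r_i")
  stopifnot(power >= 0, Z > 0, r_i > 0)
  sqrt(power * Z / (pi * log(r_o / r_i)))
}

#' Port excitation specification
#'
#' Bundles everything the waveguide-port boundary condition needs: the
#' operating frequency, input power, port annulus, the dielectric wave
#' impedance and the derived incident amplitude and propagation constant.
#'
#' @param frequency Frequency in Hz (default 2.45 GHz).
#' @param power Input power in W (default 30).
#' @param r_i,r_o Port annulus radii in m (defaults: the standard coax).
#' @param eps_dielectric Relative permittivity of the coax dielectric.
#' @param eps_tissue Complex relative permittivity of the tissue at the
#'   reference temperature (for the tissue-side propagation constant);
#'   defaults to the liver sigmoid model at 37 degC.
#' @return An object of class `mwa_source`.
#' @export
make_source <- function(frequency = 2.45e9, power = 30,
                        r_i = 0.135e-3, r_o = 0.335e-3,
                        eps_dielectric = 2.03, eps_tissue = NULL) {
  stopifnot(frequency > 0, power >= 0, r_i > 0, r_o > r_i)
  w <- 2 * pi * frequency
  k0 <- w * sqrt(.mu0 * .eps0)
  Z <- coax_wave_impedance(eps_dielectric)
  A0 <- incident_amplitude(power, Z, r_i, r_o)
  if (is.null(eps_tissue)) {
    sg <- sigmoid_coefficients()
    eps_tissue <- complex(real = permittivity_at_temperature(37, sg),
                          imaginary = -conductivity_at_temperature(37, sg) /
                            (w * .eps0))
  }
  structure(list(frequency = frequency, power = power, omega = w, k0 = k0,
                 r_i = r_i, r_o = r_o, eps_dielectric = eps_dielectric,
                 Z = Z, A0 = A0,
                 gamma0_port = complex(imaginary = k0) * sqrt(eps_dielectric),
                 gamma0_tissue = complex(imaginary = k0) * sqrt(eps_tissue)),
            class = "mwa_source")
}

#' Incident TEM field across the port annulus
#'
#' The radial electric field of the incident coax mode, magnitude `A0/r`
#' with uniform phase across the port plane.
#'
#' @param source An [make_source()] object.
#' @param r Radial coordinate(s) in m, within `[r_i, r_o]`.
#' @return Complex radial field in V/m.
#' @export
incident_field <- function(source, r) {
  if (any(r < source$r_i - 1e-15 | r > source$r_o + 1e-15))
    stop("incident_field: r outside the port annulus")
  complex(real = source$A0 / r)
}

#' Port reflection coefficient from sampled fields
#'
#' Projects the reflected field onto the incident coax mode over the port
#' annulus: `Gamma = int (E - E_inc) conj(E_inc) r dr / int |E_inc|^2 r dr`
#' (trapezoidal quadrature; the r weight is the axisymmetric measure, making
#' Gamma the modal TEM reflection coefficient).
#'
#' @param E Complex total radial field samples on the port.
#' @param E_inc Complex incident field samples at the same radii.
#' @param r Sample radii in m (ascending).
#' @return Complex reflection coefficient Gamma.
#' @export
reflection_coefficient <- function(E, E_inc, r) {
  stopifnot(length(E) == length(E_inc), length(E) == length(r), length(r) >= 2)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(r))
  den <- trapz(E_inc * Conj(E_inc) * r)
  if (abs(den) == 0) stop("reflection_coefficient: zero incident energy")
  trapz((E - E_inc) * Conj(E_inc) * r) / den
}

#' S11 in dB from a reflection coefficient
#'
#' `20 log10 |Gamma|`, floored at -160 dB for numerically zero reflection.
#'
#' @param gamma Complex reflection coefficient.
#' @return S11 in dB.
#' @export
s11_db <- function(gamma) {
  mag <- Mod(gamma)
  ifelse(mag < 1e-8, -160, 20 * log10(mag))
}

# Port and absorbing-boundary structures (cached per mesh): edge matrices,
# incident load, and for each absorbing edge the adjacent element index
# (whose material sets the local wave impedance).
.em_boundary_cache <- function(mesh, fem) {
  if (!is.null(mesh$cache$em_bnd)) return(mesh$cache$em_bnd)
  be <- mesh$boundary_edges
  port <- be[be$tag == "port", , drop = FALSE]
  abc <- be[be$tag == "outer_absorbing", , drop = FALSE]
  out <- list(has_port = nrow(port) > 0, has_abc = nrow(abc) > 0)
  inv_r <- function(r) 1 / r
  if (out$has_port) {
    out$port <- .p2_edge_matrices(mesh, fem$dofs, port, weight = inv_r)
    out$port_df <- port
  }
  if (out$has_abc) {
    out$abc <- .p2_edge_matrices(mesh, fem$dofs, abc, weight = inv_r)
    # adjacent element of each absorbing edge: the triangle containing the
    # point just inside the boundary at the edge midpoint
    mid <- (mesh$vertices[abc$v1, , drop = FALSE] +
            mesh$vertices[abc$v2, , drop = FALSE]) / 2
    dvec <- mesh$vertices[abc$v2, , drop = FALSE] -
            mesh$vertices[abc$v1, , drop = FALSE]
    nrm <- cbind(dvec[, 2], -dvec[, 1])  # one of the two normals
    nrm <- nrm / sqrt(rowSums(nrm^2))
    eps_in <- 1e-9 + 0.05 * sqrt(rowSums(dvec^2))
    tri <- .mesh_locate(mesh, mid - eps_in * nrm)
    flip <- is.na(tri)
    if (any(flip))
      tri[flip] <- .mesh_locate(mesh, mid[flip, , drop = FALSE] +
                                  eps_in[flip] * nrm[flip, , drop = FALSE])
    if (anyNA(tri)) stop("internal: absorbing edge without adjacent element")
    out$abc_elem <- tri
  }
  # essential condition u = 0 on the symmetry axis
  out$axis_dofs <- which(fem$dofs$coord[, 1] < 1e-14)
  mesh$cache$em_bnd <- out
  out
}

#' Solve the axisymmetric frequency-domain EM problem
#'
#' Assembles and solves the scalar azimuthal-H formulation of the wave
#' problem on the mesh, with the waveguide-port condition on `port` edges,
#' a first-order absorbing condition (local tissue impedance at the current
#' temperature) on `outer_absorbing` edges, natural PEC on conductor
#' surfaces and `w = 0` on the axis. The complex banded system is solved by
#' a direct LAPACK factorisation (deterministic ordering).
#'
#' @param mesh An `mwa_mesh` from [generate_mesh()].
#' @param props Per-element properties from [material_field()].
#' @param source An [make_source()] object.
#' @return An object of class `mwa_em_solution`: `u` (complex dofs of
#'   `w = r * H_phi`),
#'   `gamma` (complex reflection coefficient), `s11_db`, `Qs` (per-element
#'   loss density, W/m^3), `absorbed_power` (revolved volume integral of Qs,
#'   W), `residual` (relative linear-system residual) and the inputs.
#' @export
solve_em <- function(mesh, props, source) {
  nel <- nrow(mesh$triangles)
  if (length(props$eps_r) != nel || length(props$sigma) != nel)
    stop("solve_em: props/mesh mismatch")
  fem <- .fem_cache(mesh)
  bnd <- .em_boundary_cache(mesh, fem)
  if (!bnd$has_port) stop("solve_em: mesh has no port boundary")
  w <- source$omega; k0 <- source$k0
  epsc <- complex(real = props$eps_r, imaginary = -props$sigma / (w * .eps0))

  # volume triplets: (1/eps~) Kw - k0^2 Mw, element-wise (1/r weight)
  vv <- as.vector(fem$elem$Kw / epsc) - k0^2 * as.vector(fem$elem$Mw)
  ii <- as.vector(fem$elem$ii); jj <- as.vector(fem$elem$jj)

  # Boundary signs follow the e^{+j w t} convention consistently with
  # eps~ = eps - j sigma/(w eps0); flipping them (and the load) would give
  # the conjugate solution, indistinguishable in lossless tests but turning
  # tissue loss into gain.
  jwe <- complex(imaginary = w * .eps0)
  # port Robin term: +j w eps0 Z_p * int(w v / r ds)
  cp <- jwe * source$Z
  ii <- c(ii, as.vector(bnd$port$ii)); jj <- c(jj, as.vector(bnd$port$jj))
  vv <- c(vv, cp * as.vector(bnd$port$K))
  # absorbing term: +j w eps0 Z_local * int(w v / r ds), Z_local from the
  # adjacent element's complex permittivity
  if (bnd$has_abc) {
    Zt <- sqrt(.mu0 / .eps0) / sqrt(epsc[bnd$abc_elem])
    ii <- c(ii, as.vector(bnd$abc$ii)); jj <- c(jj, as.vector(bnd$abc$jj))
    vv <- c(vv, as.vector(bnd$abc$K * (jwe * Zt)))
  }

  # incident load: +2 j w eps0 A0 * int(v / r ds)
  ndof <- fem$dofs$ndof
  b <- complex(ndof)
  ld <- .p2_edge_load(mesh, fem$dofs, bnd$port_df, function(r) 1 / r)
  bvals <- rowsum(ld$val, ld$dof)
  b[as.integer(rownames(bvals))] <- bvals[, 1]
  b <- 2 * jwe * source$A0 * b

  u <- .banded_solve_triplets(ii, jj, vv, b, ndof, fixed = bnd$axis_dofs)

  # relative residual of the full system (axis rows excluded)
  Ax <- complex(ndof)
  contrib <- vv * u[jj]
  sums <- rowsum(cbind(Re(contrib), Im(contrib)), ii)
  rid <- as.integer(rownames(sums))
  Ax[rid] <- complex(real = sums[, 1], imaginary = sums[, 2])
  free <- setdiff(seq_len(ndof), bnd$axis_dofs)
  residual <- sqrt(sum(Mod(Ax[free] - b[free])^2)) /
    max(sqrt(sum(Mod(b[free])^2)), 1e-300)

  # port projection: Gamma = 1 - I_u / I_inc with I_u = int H_phi dr =
  # int w / r dr (3-point Gauss on each quadratic edge trace)
  pd <- bnd$port_df
  w1 <- u[fem$dofs$newid[pd$v1]]; w2 <- u[fem$dofs$newid[pd$v2]]
  wm <- u[.edge_dof(fem$dofs, pd$v1, pd$v2)]
  r1 <- mesh$vertices[pd$v1, 1]; r2 <- mesh$vertices[pd$v2, 1]
  elen <- abs(r2 - r1)
  gt <- (c(-sqrt(3 / 5), 0, sqrt(3 / 5)) + 1) / 2
  gw <- c(5, 8, 5) / 18
  I_u <- 0
  for (k in 1:3) {
    tt <- gt[k]
    wt <- w1 * (1 - tt) * (1 - 2 * tt) + w2 * tt * (2 * tt - 1) +
      wm * 4 * tt * (1 - tt)
    rt <- r1 + tt * (r2 - r1)
    I_u <- I_u + sum(gw[k] * elen * wt / rt)
  }
  I_inc <- (source$A0 / source$Z) * log(source$r_o / source$r_i)
  gamma <- if (source$power > 0) 1 - I_u / I_inc else complex(real = 0)

  # loss density and absorbed power (r-weighted element averages)
  qs <- .loss_density_elements(mesh, fem, u, epsc, props$sigma, w)

  flag <- character(0)
  if (Mod(gamma) > 1 + 1e-3) {
    flag <- sprintf("nonphysical |Gamma| = %.4f > 1", Mod(gamma))
    warning("solve_em: ", flag)
  }
  structure(list(u = u, gamma = gamma, s11_db = s11_db(gamma),
                 Qs = qs$Qs, absorbed_power = qs$P,
                 residual = residual, source = source, props = props,
                 mesh = mesh, warnings = flag),
            class = "mwa_em_solution")
}

# Per-element loss density Qs = sigma |E|^2 / 2 (r-weighted mean over the
# quadrature points) and the revolved absorbed power 2 pi int Qs r dA.
.loss_density_elements <- function(mesh, fem, u, epsc, sigma, w) {
  t <- mesh$triangles; v <- mesh$vertices
  nE <- nrow(t)
  x1 <- v[t[, 1], 1]; y1 <- v[t[, 1], 2]
  x2 <- v[t[, 2], 1]; y2 <- v[t[, 2], 2]
  x3 <- v[t[, 3], 1]; y3 <- v[t[, 3], 2]
  j11 <- x2 - x1; j12 <- x3 - x1; j21 <- y2 - y1; j22 <- y3 - y1
  det <- j11 * j22 - j12 * j21
  i11 <- j22 / det; i12 <- -j12 / det; i21 <- -j21 / det; i22 <- j11 / det
  uloc <- matrix(u[fem$dofs$dofmap], ncol = 6)
  ce <- 1 / (complex(imaginary = w * .eps0) * epsc)  # E = ce * curl(H)
  q <- .tri_quad
  num <- numeric(nE); den <- numeric(nE)
  for (k in seq_along(q$w)) {
    sh <- .p2_shape(q$xi[k], q$eta[k])
    rq <- x1 + j11 * q$xi[k] + j12 * q$eta[k]
    dxi <- as.vector(uloc %*% sh$dxi); deta <- as.vector(uloc %*% sh$deta)
    dwr <- dxi * i11 + deta * i21
    dwz <- dxi * i12 + deta * i22
    Er <- -ce * dwz / rq
    Ez <- ce * dwr / rq
    E2 <- Mod(Er)^2 + Mod(Ez)^2
    wr <- q$w[k] * det * rq
    num <- num + wr * E2
    den <- den + wr
  }
  Qs <- sigma / 2 * num / den
  list(Qs = Qs, P = 2 * pi * sum(sigma / 2 * num))
}

#' Loss density from a field solution
#'
#' The volumetric heat source from dielectric (dipole-rotation) losses,
#' `Qs = sigma |E|^2 / 2` per element in W/m^3.
#'
#' @param solution An `mwa_em_solution`.
#' @param sigma Optional per-element conductivity overriding the one the
#'   solution was computed with (S/m).
#' @return Numeric vector of per-element loss densities.
#' @export
compute_loss_density <- function(solution, sigma = NULL) {
  if (is.null(sigma)) return(solution$Qs)
  stopifnot(length(sigma) == length(solution$Qs))
  base <- solution$props$sigma
  out <- numeric(length(sigma))
  nz <- base > 0
  out[nz] <- solution$Qs[nz] * sigma[nz] / base[nz]
  if (any(!nz & sigma > 0)) {
    fem <- .fem_cache(solution$mesh)
    w <- solution$source$omega
    epsc <- complex(real = solution$props$eps_r,
                    imaginary = -solution$props$sigma / (w * .eps0))
    qs <- .loss_density_elements(solution$mesh, fem, solution$u, epsc,
                                 sigma, w)
    out <- qs$Qs
  }
  out
}

#' Evaluate the electric field and loss density at points
#'
#' Point evaluation of the meridian electric field (from the quadratic
#' H_phi interpolant) and `Qs = sigma |E|^2 / 2`, using the containing
#' element's material. Points outside the meshed domain give NA.
#'
#' @param solution An `mwa_em_solution`.
#' @param pts n x 2 matrix of (r, z) points in m.
#' @return List with complex `E_r`, `E_z`, numeric `Qs`, and the containing
#'   triangle index `tri`.
#' @export
evaluate_em_field <- function(solution, pts) {
  mesh <- solution$mesh
  fem <- .fem_cache(mesh)
  ev <- .p2_eval(mesh, fem$dofs, solution$u, pts, derivatives = TRUE)
  w <- solution$source$omega
  ok <- !is.na(ev$tri)
  E_r <- rep(NA_complex_, nrow(pts)); E_z <- E_r
  Qs <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    el <- ev$tri[ok]
    epsc <- complex(real = solution$props$eps_r[el],
                    imaginary = -solution$props$sigma[el] / (w * .eps0))
    ce <- 1 / (complex(imaginary = w * .eps0) * epsc)
    # on the axis w, w_z ~ r^2: clamp r to avoid 0/0 (fields -> 0 there)
    rr <- pmax(pts[ok, 1], 1e-9)
    E_r[ok] <- -ce * ev$dz[ok] / rr
    E_z[ok] <- ce * ev$dr[ok] / rr
    Qs[ok] <- solution$props$sigma[el] / 2 *
      (Mod(E_r[ok])^2 + Mod(E_z[ok])^2)
  }
  list(E_r = E_r, E_z = E_z, Qs = Qs, tri = ev$tri)
}

#' @exportS3Method print mwa_em_solution
print.mwa_em_solution <- function(x, ...) {
  cat("mwablate EM solution\n")
  cat(sprintf("  Gamma = %.4f %+.4fi  |Gamma| = %.4f  S11 = %.2f dB\n",
              Re(x$gamma), Im(x$gamma), Mod(x$gamma), x$s11_db))
  cat(sprintf("  input power %.1f W, absorbed %.2f W (balance %.1f%%)\n",
              x$source$power, x$absorbed_power,
              if (x$source$power > 0)
                100 * x$absorbed_power / ((1 - Mod(x$gamma)^2) * x$source$power)
              else NA_real_))
  cat(sprintf("  linear-system relative residual %.2e\n", x$residual))
  if (length(x$warnings)) cat("  warnings:", x$warnings, "\n")
  invisible(x)
}
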