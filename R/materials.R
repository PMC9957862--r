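#' Sigmoid coefficients for temperature-dependent liver dielectrics
#'
#' Coefficients of the sigmoidal regression model for the relative
#' permittivity and effective conductivity of liver tissue as functions of
#' temperature,
#' \deqn{\varepsilon_r(T) = \alpha_3\,(1 - 1/(1 + e^{\alpha_1(\alpha_2 - T)})) + 1}
#' \deqn{\sigma(T) = \beta_3\,(1 - 1/(1 + e^{\beta_1(\beta_2 - T)}))}
#' Both properties decrease monotonically with temperature; the drop is
#' centred near the water-loss transition (around 82--85 degC) and drives the
#' changing antenna match during ablation.
#'
#' The shipped defaults are the published sigmoidal fit for ex vivo bovine
#' liver at 2.45 GHz (Ji & Brace 2011): `alpha1 = 0.0764` 1/degC,
#' `alpha2 = 82.271` degC, `alpha3 = 48.391` (permittivity span);
#' `beta1 = 0.0697` 1/degC, `beta2 = 85.375` degC, `beta3 = 2.173` S/m
#' (conductivity span). All are configurable and echoed into the run
#' manifest.
#'
#' @param alpha1,alpha2,alpha3 Permittivity sigmoid rate (1/degC), centre
#'   (degC) and span (dimensionless).
#' @param beta1,beta2,beta3 Conductivity sigmoid rate (1/degC), centre
#'   (degC) and span (S/m).
#' @return An object of class `mwa_sigmoid`.
#' @export
sigmoid_coefficients <- function(alpha1 = 0.0764, alpha2 = 82.271,
                                 alpha3 = 48.391,
                                 beta1 = 0.0697, beta2 = 85.375,
                                 beta3 = 2.173) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha3 > 0, beta3 > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "mwa_sigmoid")
}

# Overflow-safe logistic sigmoid 1/(1 + exp(x)) evaluated at x = rate*(centre-T);
# saturates to 0/1 for |x| beyond ~700 where exp() would overflow.
.sat_sigmoid <- function(x) {
  out <- numeric(length(x))
  hi <- x > 700
  lo <- x < -700
  mid <- !hi & !lo
  out[mid] <- 1 / (1 + exp(x[mid]))
  out[hi] <- 0
  out[lo] <- 1
  out
}

#' Liver relative permittivity at temperature
#'
#' Evaluates the sigmoidal permittivity model; strictly decreasing in `T`,
#' tending to `alpha3 + 1` at low temperature and to 1 (vacuum) as tissue
#' water is lost at high temperature.
#'
#' @param T Temperature in degC (vectorised).
#' @param coef A [sigmoid_coefficients()] object.
#' @return Relative permittivity (dimensionless), same length as `T`.
#' @export
permittivity_at_temperature <- function(T, coef = sigmoid_coefficients()) {
  stopifnot(all(is.finite(T)))
  s <- .sat_sigmoid(coef$alpha1 * (coef$alpha2 - T)) # = 1/(1+exp(a1(a2-T)))
  coef$alpha3 * (1 - s) + 1
}

#' Liver effective conductivity at temperature
#'
#' Evaluates the sigmoidal conductivity model; strictly decreasing in `T`,
#' tending to `beta3` at low temperature and to 0 at high temperature.
#'
#' @inheritParams permittivity_at_temperature
#' @return Effective conductivity in S/m, same length as `T`.
#' @export
conductivity_at_temperature <- function(T, coef = sigmoid_coefficients()) {
  stopifnot(all(is.finite(T)))
  s <- .sat_sigmoid(coef$beta1 * (coef$beta2 - T))
  coef$beta3 * (1 - s)
}

#' Material assignment for a simulation
#'
#' Static dielectric properties per region plus the temperature-dependent
#' liver model for the tissue region, and the liver thermal constants.
#' Non-tissue defaults: PTFE coax dielectric (eps_r 2.03, lossless),
#' polymer catheter (eps_r 2.6, lossless); the slot fill is coax dielectric
#' extended to the catheter, the SSS sleeve gap fill is catheter material.
#' Liver thermal constants: density 1060 kg/m^3, specific heat 3600
#' J/(kg degC), thermal conductivity 0.512 W/(m degC), held constant with
#' temperature. Relative permeability is 1 everywhere (non-magnetic tissue).
#'
#' In `property_mode = "constant"` the tissue dielectric properties are
#' frozen at their 37 degC values for the whole simulation; in `"dynamic"`
#' they follow the sigmoid model as the tissue heats.
#'
#' @param sigmoid A [sigmoid_coefficients()] object for the tissue region.
#' @param eps_dielectric,eps_catheter Relative permittivities of the coax
#'   dielectric and catheter.
#' @param sigma_dielectric,sigma_catheter Conductivities (S/m) of the same.
#' @param rho,C,k_l Liver density (kg/m^3), specific heat (J/(kg degC)) and
#'   thermal conductivity (W/(m degC)).
#' @param property_mode `"dynamic"` or `"constant"`.
#' @param T_ref Reference temperature (degC) used for the constant mode and
#'   the initial condition.
#' @return An object of class `mwa_materials`.
#' @export
default_materials <- function(sigmoid = sigmoid_coefficients(),
                              eps_dielectric = 2.03, sigma_dielectric = 0,
                              eps_catheter = 2.6, sigma_catheter = 0,
                              rho = 1060, C = 3600, k_l = 0.512,
                              property_mode = c("dynamic", "constant"),
                              T_ref = 37) {
  property_mode <- match.arg(property_mode)
  stopifnot(eps_dielectric >= 1, eps_catheter >= 1,
            sigma_dielectric >= 0, sigma_catheter >= 0,
            rho > 0, C > 0, k_l > 0)
  static <- list(
    coax_dielectric = list(eps_r = eps_dielectric, sigma = sigma_dielectric),
    slot_fill       = list(eps_r = eps_dielectric, sigma = sigma_dielectric),
    catheter        = list(eps_r = eps_catheter, sigma = sigma_catheter),
    sleeve_gap_fill = list(eps_r = eps_catheter, sigma = sigma_catheter)
  )
  structure(list(static = static, sigmoid = sigmoid,
                 thermal = list(rho = rho, C = C, k_l = k_l),
                 property_mode = property_mode, T_ref = T_ref,
                 mu_r = 1),
            class = "mwa_materials")
}

#' Per-element dielectric properties on a mesh
#'
#' Evaluates (eps_r, sigma) for every element of a mesh: non-tissue elements
#' take their static values; tissue elements take the sigmoid model at the
#' element temperature (mean of its vertex temperatures). In constant mode
#' the tissue values are those at the reference temperature regardless of
#' `T`.
#'
#' @param mesh An `mwa_mesh`.
#' @param T Nodal temperature field in degC: either a single number (uniform)
#'   or a vector over the mesh vertices (an `mwa_thermal_state` is also
#'   accepted).
#' @param materials An [default_materials()] object.
#' @return List with numeric vectors `eps_r` and `sigma`, one value per
#'   element.
#' @export
material_field <- function(mesh, T, materials = default_materials()) {
  nv <- nrow(mesh$vertices)
  if (inherits(T, "mwa_thermal_state")) T <- T$T
  if (length(T) == 1) T <- rep(T, nv)
  if (length(T) != nv)
    stop("dimension error: temperature has length ", length(T),
         " but the mesh has ", nv, " vertices")

  nel <- nrow(mesh$triangles)
  eps <- numeric(nel)
  sig <- numeric(nel)
  regions <- mesh$region_names[mesh$region_id]
  for (nm in unique(regions)) {
    idx <- regions == nm
    if (nm == "tissue") {
      Tel <- if (materials$property_mode == "constant")
        rep(materials$T_ref, sum(idx))
      else
        rowMeans(matrix(T[mesh$triangles[idx, , drop = FALSE]], ncol = 3))
      eps[idx] <- permittivity_at_temperature(Tel, materials$sigmoid)
      sig[idx] <- conductivity_at_temperature(Tel, materials$sigmoid)
    } else {
      st <- materials$static[[nm]]
      if (is.null(st))
        stop("no static material defined for region '", nm, "'")
      eps[idx] <- st$eps_r
      sig[idx] <- st$sigma
    }
  }
  list(eps_r = eps, sigma = sig)
}

#' @exportS3Method print mwa_materials
print.mwa_materials <- function(x, ...) {
  cat("mwablate materials (property mode:", x$property_mode, ")\n")
  cat(sprintf("  tissue @ %.0f degC: eps_r = %.2f, sigma = %.3f S/m\n",
              x$T_ref,
              permittivity_at_temperature(x$T_ref, x$sigmoid),
              conductivity_at_temperature(x$T_ref, x$sigmoid)))
  for (nm in names(x$static))
    cat(sprintf("  %-16s eps_r = %.2f, sigma = %.2f S/m\n", nm,
                x$static[[nm]]$eps_r, x$static[[nm]]$sigma))
  cat(sprintf("  thermal: rho = %.0f kg/m^3, C = %.0f J/(kg degC), k = %.3f W/(m degC)\n",
              x$thermal$rho, x$thermal$C, x$thermal$k_l))
  invisible(x)
}
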