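# Hagen-Poiseuille capillary flow: velocities, wall shear and Reynolds
# number. Used to certify that pumping a sample through the capillary
# does not apply enough shear to rip off flagella (which would destroy
# the very motility being measured).
#
# All core functions work in SI units (m, s, Pa); constructors accept
# the bench units (mm, ml/min, mPa s) and convert.

#' Capillary and fluid specification
#'
#' @param diameter inner diameter, m.
#' @param flow_rate volumetric flow, m^3/s.
#' @param length capillary length, m.
#' @param dynamic_viscosity eta, Pa s.
#' @param kinematic_viscosity nu, m^2/s.
#' @param density rho, kg/m^3.
#' @details Any two of (eta, nu, rho) determine the third via
#'   `eta = rho * nu`; if all three are supplied they must agree to
#'   0.1%. Defaults describe a dilute aqueous broth at ~35 C.
#' @return A `capillary_spec`.
#' @export
capillary_spec <- function(diameter, flow_rate, length = 0.6,
                           dynamic_viscosity = 7.2e-4,
                           kinematic_viscosity = NULL,
                           density = 993) {
  stopifnot(diameter > 0, flow_rate > 0, length > 0)
  eta <- dynamic_viscosity; nu <- kinematic_viscosity; rho <- density
  if (is.null(nu) && !is.null(eta) && !is.null(rho)) nu <- eta / rho
  if (is.null(eta) && !is.null(nu) && !is.null(rho)) eta <- nu * rho
  if (is.null(rho) && !is.null(eta) && !is.null(nu)) rho <- eta / nu
  if (is.null(eta) || is.null(nu) || is.null(rho))
    stop("need at least two of dynamic_viscosity, kinematic_viscosity, density")
  stopifnot(eta > 0, nu > 0, rho > 0)
  if (abs(eta - rho * nu) / eta > 0.001)
    stop("inconsistent fluid properties: eta != rho * nu (>0.1%)")
  structure(list(diameter = diameter, flow_rate = flow_rate,
                 length = length, dynamic_viscosity = eta,
                 kinematic_viscosity = nu, density = rho),
            class = "capillary_spec")
}

#' Capillary specification in bench units
#'
#' @param diameter_mm inner diameter, mm.
#' @param flow_ml_min flow rate, ml/min.
#' @param viscosity_mpas dynamic viscosity, mPa s.
#' @param density density, kg/m^3.
#' @param length_m capillary length, m.
#' @return A [capillary_spec()].
#' @export
capillary_spec_bench <- function(diameter_mm, flow_ml_min,
                                 viscosity_mpas = 0.72, density = 993,
                                 length_m = 0.6) {
  capillary_spec(diameter = diameter_mm / 1000,
                 flow_rate = flow_ml_min * 1e-6 / 60,
                 length = length_m,
                 dynamic_viscosity = viscosity_mpas / 1000,
                 density = density)
}

#' Cross-section mean velocity of laminar pipe flow
#'
#' `u_m = 4 Q / (pi D^2)`: the flow rate divided by the cross-section
#' area.
#'
#' @param flow_rate Q, m^3/s (>= 0).
#' @param diameter D, m (> 0).
#' @return u_m in m/s.
#' @export
mean_velocity <- function(flow_rate, diameter) {
  if (flow_rate < 0 || diameter <= 0)
    stop("flow_rate must be >= 0 and diameter > 0")
  4 * flow_rate / (pi * diameter^2)
}

#' Parabolic (Poiseuille) velocity profile
#'
#' `u(y) = 2 u_m (1 - (2y/D)^2)` with `y` measured from the capillary
#' axis: `u(0) = u_max = 2 u_m`, `u(D/2) = 0` (no slip at the wall).
#'
#' @param u_m mean velocity, m/s.
#' @param y radial position from the centreline, m; `|y| <= D/2`.
#' @param diameter D, m.
#' @return u(y) in m/s.
#' @export
velocity_profile <- function(u_m, y, diameter) {
  if (any(abs(y) > diameter / 2))
    stop("|y| must not exceed the capillary radius")
  2 * u_m * (1 - (2 * y / diameter)^2)
}

#' Wall shear rate of Poiseuille flow
#'
#' Magnitude of the profile derivative at the wall:
#' `gamma_dot = 8 u_m / D`.
#'
#' @param u_m mean velocity, m/s (> 0).
#' @param diameter D, m (> 0).
#' @return gamma_dot in 1/s.
#' @export
wall_shear_rate <- function(u_m, diameter) {
  if (u_m <= 0 || diameter <= 0) stop("inputs must be positive")
  8 * u_m / diameter
}

#' Newtonian shear stress
#'
#' `tau = eta * gamma_dot`.
#'
#' @param eta dynamic viscosity, Pa s (>= 0).
#' @param gamma_dot shear rate, 1/s (>= 0).
#' @return tau in Pa.
#' @export
shear_stress <- function(eta, gamma_dot) {
  if (eta < 0 || gamma_dot < 0) stop("inputs must be non-negative")
  eta * gamma_dot
}

#' Reynolds number and flow-regime check
#'
#' `Re = u_m D / nu`; flow is taken as laminar when `Re < 2300`.
#'
#' @param u_m mean velocity, m/s (> 0).
#' @param diameter D, m (> 0).
#' @param nu kinematic viscosity, m^2/s (> 0).
#' @return A list: `reynolds`, `laminar` (logical).
#' @export
reynolds_number <- function(u_m, diameter, nu) {
  if (u_m <= 0 || diameter <= 0 || nu <= 0)
    stop("inputs must be positive")
  re <- u_m * diameter / nu
  list(reynolds = re, laminar = re < 2300)
}

#' Full flow-field report for a capillary
#'
#' Composes the mean/maximum velocity, wall shear rate and stress, and
#' Reynolds number for one capillary specification.
#'
#' @param spec a [capillary_spec()].
#' @return A `flow_field`: `u_m`, `u_max` (= 2 u_m), `wall_shear_rate`,
#'   `wall_shear_stress`, `reynolds`, `laminar`.
#' @export
capillary_report <- function(spec) {
  stopifnot(inherits(spec, "capillary_spec"))
  u_m <- mean_velocity(spec$flow_rate, spec$diameter)
  g <- wall_shear_rate(u_m, spec$diameter)
  re <- reynolds_number(u_m, spec$diameter, spec$kinematic_viscosity)
  structure(list(u_m = u_m, u_max = 2 * u_m, wall_shear_rate = g,
                 wall_shear_stress = shear_stress(
                   spec$dynamic_viscosity, g),
                 reynolds = re$reynolds, laminar = re$laminar),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field>\n  u_m    %.4g m/s (%.1f mm/s)\n  u_max  %.4g m/s (%.1f mm/s)\n",
              x$u_m, x$u_m * 1000, x$u_max, x$u_max * 1000))
  cat(sprintf("  wall shear rate   %.4g 1/s\n  wall shear stress %.4g Pa\n",
              x$wall_shear_rate, x$wall_shear_stress))
  cat(sprintf("  Re %.4g (%s)\n", x$reynolds,
              if (x$laminar) "laminar" else "not laminar"))
  invisible(x)
}
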