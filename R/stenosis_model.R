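#' Quadratic stenosis pressure-drop model
#'
#' A stenosis is represented as a nonlinear resistor with pressure drop
#' dP = C1 q + C2 q^2: a viscous term linear in the flow and an expansion
#' (separation) loss quadratic in the flow. The flow-dependent resistance is
#' R(q) = dP / q = C1 + C2 q.
#'
#' @param C1 viscous coefficient (Pa.s.m^-3), >= 0.
#' @param C2 expansion coefficient (Pa.s^2.m^-6), >= 0. Not both zero.
#' @return an object of class `stenosis_model`.
#' @export
stenosis_model <- function(C1, C2) {
  if (C1 < 0 || C2 < 0) stop_domain("C1 and C2 must be non-negative")
  if (C1 == 0 && C2 == 0) stop_domain("C1 and C2 cannot both be zero")
  structure(list(C1 = as.numeric(C1), C2 = as.numeric(C2)),
            class = "stenosis_model")
}

#' @export
print.stenosis_model <- function(x, ...) {
  cat(sprintf("<stenosis_model> C1 = %.4g Pa.s.m^-3, C2 = %.4g Pa.s^2.m^-6\n",
              x$C1, x$C2))
  invisible(x)
}

#' Pressure drop across a stenosis
#'
#' @param model a [stenosis_model()].
#' @param q flow (m^3/s), >= 0; vectorized. Reverse flow through a stenosis
#'   is outside the model's scope and rejected.
#' @return pressure drop C1 q + C2 q^2 (Pa).
#' @export
stenosis_pressure_drop <- function(model, q) {
  if (any(q < 0)) stop_domain("reverse flow through a stenosis is not modelled")
  model$C1 * q + model$C2 * q^2
}

#' Flow-dependent stenosis resistance
#'
#' @inheritParams stenosis_pressure_drop
#' @return R(q) = C1 + C2 q (Pa.s.m^-3); equals dP/q for q > 0, and the
#'   linear limit C1 at q = 0.
#' @export
stenosis_flow_resistance <- function(model, q) {
  if (any(q < 0)) stop_domain("reverse flow through a stenosis is not modelled")
  model$C1 + model$C2 * q
}

#' Default stenosis coefficients from geometry
#'
#' The classical viscous + sudden-expansion decomposition: C1 is the
#' Poiseuille resistance integrated over the stenosed interval (with the
#' cosine area taper imposed), and C2 = Kt rho / 2 * (1/A_s - 1/A_0)^2 with
#' A_0 the healthy lumen area, A_s the minimum lumen area and Kt an
#' empirical expansion-loss coefficient.
#'
#' @param profile the healthy [lumen_profile()].
#' @param sten a [stenosis_spec()] lying within the profile.
#' @param mu viscosity (Pa.s); default the high-shear blood asymptote.
#' @param rho blood density (kg/m^3).
#' @param Kt expansion-loss coefficient (dimensionless); the 1.52 default is
#'   the classical empirical value for smooth axisymmetric constrictions.
#' @param step_m quadrature step for the viscous integral (m).
#' @return a [stenosis_model()].
#' @export
default_coefficients <- function(profile, sten, mu = 0.0035, rho = 1050,
                                 Kt = 1.52, step_m = 5e-5) {
  stopifnot(inherits(profile, "lumen_profile"), inherits(sten, "stenosis_spec"))
  if (sten$area_ratio >= 1)
    stop_domain("degenerate stenosis: area_ratio must be < 1")
  from <- sten$center_m - sten$length_m / 2
  to <- sten$center_m + sten$length_m / 2
  C1 <- segment_viscous_resistance(profile, mu, from, to,
                                   stenoses = list(sten), step_m = step_m)
  d0 <- profile_diameter(profile, sten$center_m)
  A0 <- pi * d0^2 / 4
  As <- sten$area_ratio * A0
  C2 <- Kt * rho / 2 * (1 / As - 1 / A0)^2
  stenosis_model(C1, C2)
}

#' Calibrate stenosis coefficients from two observations
#'
#' Solves the 2x2 linear system dP_i = C1 q_i + C2 q_i^2 for (C1, C2) from
#' two (flow, pressure-drop) pairs, e.g. an external CFD or pressure-wire
#' characterization of a lesion.
#'
#' @param q two distinct positive flows (m^3/s).
#' @param dP the corresponding pressure drops (Pa).
#' @return a [stenosis_model()]; errors if the system is singular or a
#'   coefficient comes out negative (non-physical).
#' @export
calibrate_coefficients <- function(q, dP) {
  if (length(q) != 2L || length(dP) != 2L)
    stop_domain("exactly two (q, dP) observations are required")
  if (any(q <= 0)) stop_domain("flows must be positive")
  if (abs(q[1] - q[2]) <= 1e-15 * max(q))
    stop_domain("calibration flows must be distinct")
  A <- cbind(q, q^2)
  coef <- solve(A, dP)
  if (any(coef < -1e-9 * max(abs(coef), 1)))
    stop_domain("calibration yields a negative coefficient (non-physical)")
  stenosis_model(max(coef[1], 0), max(coef[2], 0))
}
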