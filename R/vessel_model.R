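#' Lumen profile of a vessel segment
#'
#' A sampled description of the lumen along a vessel centerline: arc-length
#' positions and the lumen diameter at each position. This is the healthy
#' (pre-stenotic) geometry; stenoses are described separately by
#' [stenosis_spec()] and imposed on the profile when hydraulic quantities are
#' computed. Between samples the diameter is linearly interpolated.
#'
#' @param arc_length_m strictly increasing numeric vector of centerline
#'   positions (m), at least two samples.
#' @param diameter_m positive numeric vector of lumen diameters (m), same
#'   length as `arc_length_m`.
#' @return an object of class `lumen_profile`.
#' @examples
#' lumen_profile(c(0, 0.075), c(0.003, 0.003))  # straight 3 mm vessel
#' @export
lumen_profile <- function(arc_length_m, diameter_m) {
  if (length(arc_length_m) < 2L)
    stop_domain("lumen profile needs at least 2 samples")
  if (length(arc_length_m) != length(diameter_m))
    stop_domain("arc_length_m and diameter_m must have equal length")
  if (any(diff(arc_length_m) <= 0))
    stop_domain("arc_length_m must be strictly increasing")
  if (any(diameter_m <= 0))
    stop_domain("diameters must be positive")
  structure(list(arc_length_m = as.numeric(arc_length_m),
                 diameter_m = as.numeric(diameter_m)),
            class = "lumen_profile")
}

#' @export
print.lumen_profile <- function(x, ...) {
  cat(sprintf("<lumen_profile> %d samples, extent %.1f-%.1f mm, d %.2f-%.2f mm\n",
              length(x$arc_length_m),
              m_to_mm(min(x$arc_length_m)), m_to_mm(max(x$arc_length_m)),
              m_to_mm(min(x$diameter_m)), m_to_mm(max(x$diameter_m))))
  invisible(x)
}

profile_extent <- function(profile) range(profile$arc_length_m)

#' Interpolate lumen diameter at arbitrary positions
#'
#' @param profile a [lumen_profile()].
#' @param s numeric vector of arc-length positions (m) within the profile
#'   extent.
#' @param stenoses optional list of [stenosis_spec()]; when given, the cosine
#'   area taper of each stenosis is imposed on the healthy profile.
#' @return lumen diameters (m) at `s`.
#' @export
profile_diameter <- function(profile, s, stenoses = NULL) {
  ext <- profile_extent(profile)
  if (any(s < ext[1] - 1e-12 | s > ext[2] + 1e-12))
    stop_domain("position outside profile extent")
  d <- stats::approx(profile$arc_length_m, profile$diameter_m, xout = s,
                     rule = 2)$y
  if (!is.null(stenoses) && length(stenoses)) {
    a <- pi * d^2 / 4
    for (st in stenoses) {
      half <- st$length_m / 2
      inside <- abs(s - st$center_m) <= half
      if (any(inside)) {
        # cosine taper of lumen AREA: healthy at both shoulders, minimum at
        # the throat, C1-smooth at both ends
        w <- cos(pi * (s[inside] - st$center_m) / st$length_m)^2
        a[inside] <- a[inside] * (1 - (1 - st$area_ratio) * w)
      }
    }
    d <- sqrt(4 * a / pi)
  }
  d
}

#' Stenosis specification
#'
#' A focal narrowing of the main vessel, parameterized as the field reports
#' lesions: where it sits, how long it is, and its minimum lumen area as a
#' fraction of the healthy lumen area. The lumen shape across the lesion is a
#' cosine taper of area between the healthy and minimum values.
#'
#' @param center_m arc-length position of the throat (m).
#' @param length_m lesion length L (m), > 0.
#' @param area_ratio minimum lumen area / healthy lumen area, in (0, 1).
#' @return an object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(center_m, length_m, area_ratio) {
  if (length_m <= 0) stop_domain("stenosis length must be positive")
  if (area_ratio <= 0 || area_ratio >= 1)
    stop_domain("area_ratio must lie strictly between 0 and 1")
  structure(list(center_m = as.numeric(center_m),
                 length_m = as.numeric(length_m),
                 area_ratio = as.numeric(area_ratio)),
            class = "stenosis_spec")
}

#' Outlet specification
#'
#' A linear resistance boundary condition: the outlet pressure follows from
#' the flow through the terminal resistance, P_out = R_out * q (venous
#' reference pressure taken as zero).
#'
#' @param resistance_Pa_s_m3 hydraulic resistance (Pa.s.m^-3), > 0.
#' @param label identifier used in solution tables.
#' @return an object of class `outlet_spec`.
#' @export
outlet_spec <- function(resistance_Pa_s_m3, label = "outlet") {
  if (!is.finite(resistance_Pa_s_m3) || resistance_Pa_s_m3 <= 0)
    stop_domain("outlet resistance must be positive and finite")
  structure(list(resistance_Pa_s_m3 = as.numeric(resistance_Pa_s_m3),
                 label = as.character(label)),
            class = "outlet_spec")
}

#' Side-branch specification
#'
#' A side branch leaving the main vessel. In the lumped model the branch is a
#' shunt from its ostium to the venous reference through its outlet
#' resistance; the branching angle is kept as metadata only, since a
#' zero-dimensional network carries no momentum.
#'
#' @param attach_m arc-length position of the ostium on the parent (m).
#' @param diameter_m ostium diameter (m), > 0.
#' @param outlet an [outlet_spec()] for the branch's distal bed.
#' @param angle_deg branching angle (degrees); metadata only.
#' @return an object of class `side_branch_spec`.
#' @export
side_branch_spec <- function(attach_m, diameter_m, outlet,
                             angle_deg = NA_real_) {
  if (diameter_m <= 0) stop_domain("branch diameter must be positive")
  stopifnot(inherits(outlet, "outlet_spec"))
  structure(list(attach_m = as.numeric(attach_m),
                 diameter_m = as.numeric(diameter_m),
                 angle_deg = as.numeric(angle_deg),
                 outlet = outlet),
            class = "side_branch_spec")
}

#' Vessel tree
#'
#' The hydraulic domain: a main vessel with a lumen profile, zero or more
#' stenoses, zero or more side branches, a prescribed inlet pressure, and a
#' resistance outlet at the distal end of the main vessel.
#'
#' @param main_vessel a [lumen_profile()].
#' @param inlet_pressure_Pa inlet (aortic) pressure (Pa), > 0.
#' @param main_outlet an [outlet_spec()] at the distal end of the main vessel.
#' @param stenoses list of [stenosis_spec()] (may be empty).
#' @param side_branches list of [side_branch_spec()] (may be empty).
#' @return an object of class `vessel_tree`. Stenoses and branches are stored
#'   sorted by position.
#' @export
vessel_tree <- function(main_vessel, inlet_pressure_Pa, main_outlet,
                        stenoses = list(), side_branches = list()) {
  stopifnot(inherits(main_vessel, "lumen_profile"),
            inherits(main_outlet, "outlet_spec"))
  if (inlet_pressure_Pa <= 0) stop_domain("inlet pressure must be positive")
  ext <- profile_extent(main_vessel)
  for (st in stenoses) {
    stopifnot(inherits(st, "stenosis_spec"))
    if (st$center_m - st$length_m / 2 < ext[1] - 1e-12 ||
        st$center_m + st$length_m / 2 > ext[2] + 1e-12)
      stop_domain("stenosis extends outside the main vessel")
  }
  for (sb in side_branches) {
    stopifnot(inherits(sb, "side_branch_spec"))
    if (sb$attach_m < ext[1] - 1e-12 || sb$attach_m > ext[2] + 1e-12)
      stop_domain("side-branch attach position outside the main vessel")
  }
  if (length(stenoses))
    stenoses <- stenoses[order(vapply(stenoses, `[[`, 0, "center_m"))]
  if (length(side_branches))
    side_branches <- side_branches[order(vapply(side_branches, `[[`, 0,
                                                "attach_m"))]
  structure(list(main_vessel = main_vessel,
                 stenoses = stenoses,
                 side_branches = side_branches,
                 inlet_pressure_Pa = as.numeric(inlet_pressure_Pa),
                 main_outlet = main_outlet),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf(paste0("<vessel_tree> main vessel %.1f mm, %d stenosis(es), ",
                     "%d side branch(es), P_in %.1f mmHg\n"),
              m_to_mm(diff(profile_extent(x$main_vessel))),
              length(x$stenoses), length(x$side_branches),
              Pa_to_mmHg(x$inlet_pressure_Pa)))
  invisible(x)
}

#' Carreau viscosity model parameters
#'
#' Shear-thinning blood rheology: viscosity decays from the zero-shear
#' plateau `mu_0` to the infinite-shear asymptote `mu_inf` with time constant
#' `lambda_s` and power-law index `n_index`. Defaults are a whole-blood fit
#' over shear rates 0.01-50 s^-1.
#'
#' @param mu_inf infinite-shear viscosity (Pa.s).
#' @param mu_0 zero-shear viscosity (Pa.s), > `mu_inf`.
#' @param lambda_s time constant (s), > 0.
#' @param n_index power-law index; in (0, 1) for shear-thinning.
#' @return an object of class `carreau_params`.
#' @export
carreau_params <- function(mu_inf = 0.0035, mu_0 = 0.25, lambda_s = 25,
                           n_index = 0.25) {
  if (mu_inf <= 0 || mu_0 <= mu_inf)
    stop_domain("need mu_0 > mu_inf > 0")
  if (lambda_s <= 0) stop_domain("lambda_s must be positive")
  if (n_index <= 0 || n_index >= 1)
    stop_domain("n_index must lie in (0, 1) for shear-thinning blood")
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, lambda_s = lambda_s,
                 n_index = n_index),
            class = "carreau_params")
}

#' Carreau apparent viscosity
#'
#' mu(S) = mu_inf + (mu_0 - mu_inf) * (1 + (lambda * S)^2)^((n - 1) / 2).
#' Monotone non-increasing in the shear rate for n < 1, bounded by
#' \[mu_inf, mu_0\].
#'
#' @param shear_rate_s shear rate S (s^-1), >= 0; vectorized.
#' @param params a [carreau_params()].
#' @return apparent viscosity (Pa.s).
#' @examples
#' carreau_viscosity(0)      # zero-shear plateau, 0.25 Pa.s
#' carreau_viscosity(1000)   # near the 0.0035 Pa.s asymptote
#' @export
carreau_viscosity <- function(shear_rate_s, params = carreau_params()) {
  if (any(shear_rate_s < 0)) stop_domain("shear rate must be non-negative")
  params$mu_inf + (params$mu_0 - params$mu_inf) *
    (1 + (params$lambda_s * shear_rate_s)^2)^((params$n_index - 1) / 2)
}

#' Hagen-Poiseuille resistance of a straight segment
#'
#' R = 128 mu L / (pi d^4) for fully developed laminar flow.
#'
#' @param length_m segment length (m), > 0.
#' @param diameter_m lumen diameter (m), > 0.
#' @param mu dynamic viscosity (Pa.s), > 0.
#' @return hydraulic resistance (Pa.s.m^-3).
#' @export
poiseuille_resistance <- function(length_m, diameter_m, mu) {
  if (any(length_m <= 0) || any(diameter_m <= 0) || any(mu <= 0))
    stop_domain("length, diameter and viscosity must be positive")
  128 * mu * length_m / (pi * diameter_m^4)
}

# Quadrature grid: union of global step multiples, profile sample points and
# the interval endpoints. Anchoring the step grid at s = 0 (not at `from`)
# makes the trapezoid rule exactly additive over contiguous sub-intervals.
quadrature_grid <- function(profile, from_s, to_s, step) {
  k0 <- ceiling(from_s / step - 1e-9)
  k1 <- floor(to_s / step + 1e-9)
  g <- if (k1 >= k0) seq(k0, k1) * step else numeric(0)
  s <- profile$arc_length_m
  g <- c(g, s[s > from_s & s < to_s], from_s, to_s)
  g <- sort(unique(round(g, 12)))
  g <- g[g >= from_s - 1e-12 & g <= to_s + 1e-12]
  # pin the endpoints so downstream interpolation sees the exact interval
  g[1] <- from_s
  g[length(g)] <- to_s
  g
}

#' Viscous resistance of a vessel interval by quadrature
#'
#' Integrates the Poiseuille resistance density 128 mu / (pi d(s)^4) along the
#' centerline with the composite trapezoid rule. The quadrature grid is the
#' union of a fixed global step grid, the profile's own sample points, and the
#' interval endpoints, so the result is exactly additive over contiguous
#' sub-intervals and reduces to [poiseuille_resistance()] for a constant
#' diameter.
#'
#' @param profile a [lumen_profile()] (healthy geometry).
#' @param mu dynamic viscosity (Pa.s).
#' @param from_s,to_s interval bounds (m), `from_s < to_s`, within the
#'   profile extent.
#' @param stenoses optional list of [stenosis_spec()] imposed on the profile.
#' @param step_m quadrature step (m); default 0.05 mm.
#' @return hydraulic resistance (Pa.s.m^-3).
#' @export
segment_viscous_resistance <- function(profile, mu, from_s, to_s,
                                       stenoses = NULL, step_m = 5e-5) {
  ext <- profile_extent(profile)
  if (from_s >= to_s) stop_domain("need from_s < to_s")
  if (from_s < ext[1] - 1e-12 || to_s > ext[2] + 1e-12)
    stop_domain("interval outside profile extent")
  if (mu <= 0) stop_domain("viscosity must be positive")
  g <- quadrature_grid(profile, from_s, to_s, step_m)
  d <- profile_diameter(profile, pmin(pmax(g, ext[1]), ext[2]), stenoses)
  f <- 128 * mu / (pi * d^4)
  sum(diff(g) * (f[-length(f)] + f[-1]) / 2)
}
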