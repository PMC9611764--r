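#' Virtual FFR pullback along the main vessel
#'
#' Reconstructs the pressure (and FFR = P(s) / P_in) at every arc-length
#' position along the main vessel of a solved tree, mimicking the pullback of
#' a pressure wire. Within each inter-branch section the viscous drop is
#' accumulated by quadrature at the local section flow; each stenosis's total
#' drop q (C1 + C2 q) is distributed across its extent in proportion to the
#' traversed fraction of its viscous resistance, so the curve falls smoothly
#' across a lesion and is flat over healthy segments when their resistance is
#' neglected.
#'
#' @param tree the [vessel_tree()] that was solved.
#' @param solution the matching [solve_tree()] result.
#' @param step_m sampling step along the centerline (m); default 0.5 mm.
#' @return an object of class `pullback_curve`: `s_m`, `pressure_Pa`, `FFR`
#'   (starting at exactly 1 at the inlet and non-increasing), and
#'   `section_flows` (m^3/s, piecewise-constant between junctions).
#' @export
virtual_pullback <- function(tree, solution, step_m = 5e-4) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (!inherits(solution, "network_solution") || !isTRUE(solution$converged))
    stop("pullback requires a converged network_solution")
  config <- solution$config
  ladder <- build_ladder(tree, config)
  s_all <- numeric(0); p_all <- numeric(0)
  for (k in seq_along(ladder$sections)) {
    sec <- ladder$sections[[k]]
    qk <- solution$section_flows[k]
    Pk <- solution$node_pressures_Pa[k]
    grid <- quadrature_grid(tree$main_vessel, sec$from, sec$to,
                            config$quad_step_m)
    sten_in <- Filter(function(st) st$center_m >= sec$from &&
                        st$center_m < sec$to, tree$stenoses)
    d <- profile_diameter(tree$main_vessel, grid, sten_in)
    dens <- 128 * config$mu / (pi * d^4)
    cumR <- c(0, cumsum(diff(grid) * (dens[-length(dens)] + dens[-1]) / 2))
    s_samp <- unique(c(seq(sec$from, sec$to, by = step_m), sec$to))
    cum_at <- stats::approx(grid, cumR, xout = s_samp, rule = 2)$y
    # viscous part: full cumulative, or only the stenotic share when healthy
    # resistance is neglected
    visc <- cum_at
    exp_drop <- rep(0, length(s_samp))
    if (config$neglect_healthy_resistance) visc <- rep(0, length(s_samp))
    for (i in seq_along(sten_in)) {
      st <- sten_in[[i]]
      m <- sec$stenoses[[i]]
      a <- st$center_m - st$length_m / 2
      b <- st$center_m + st$length_m / 2
      Ca <- stats::approx(grid, cumR, xout = a, rule = 2)$y
      Cb <- stats::approx(grid, cumR, xout = b, rule = 2)$y
      frac <- (pmin(pmax(cum_at, Ca), Cb) - Ca) / (Cb - Ca)
      if (config$neglect_healthy_resistance)
        visc <- visc + frac * m$C1
      exp_drop <- exp_drop + frac * m$C2 * qk
    }
    p <- Pk - qk * (visc + exp_drop)
    keep <- if (k == 1) TRUE else s_samp > sec$from
    s_all <- c(s_all, s_samp[keep]); p_all <- c(p_all, p[keep])
  }
  structure(list(s_m = s_all,
                 pressure_Pa = p_all,
                 FFR = p_all / tree$inlet_pressure_Pa,
                 section_flows = solution$section_flows),
            class = "pullback_curve")
}

#' @export
print.pullback_curve <- function(x, ...) {
  cat(sprintf("<pullback_curve> %d samples, FFR %.3f -> %.3f\n",
              length(x$s_m), x$FFR[1], x$FFR[length(x$FFR)]))
  invisible(x)
}

#' @export
as.data.frame.pullback_curve <- function(x, ...) {
  data.frame(s_mm = m_to_mm(x$s_m),
             pressure_mmHg = Pa_to_mmHg(x$pressure_Pa),
             FFR = x$FFR)
}

#' Compare FFR with and without side branches
#'
#' Solves the tree as given and a pruned copy with every side branch removed
#' but the identical distal main-vessel resistance — the comparison rule for
#' isolating the hemodynamic effect of branch flow: the distal bed is held
#' fixed, only the shunts disappear.
#'
#' @param tree a [vessel_tree()] with at least one side branch.
#' @param config a [solver_config()].
#' @return an object of class `branch_comparison`: `ffr_with`, `ffr_without`,
#'   `delta_ffr` (without minus with, >= 0 when branches sit at or downstream
#'   of the lesions), inlet flows, and both per-section main-vessel flow
#'   profiles on the sections of the branched tree.
#' @export
compare_with_without <- function(tree, config = solver_config()) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (!length(tree$side_branches))
    stop_domain("comparison requires at least one side branch")
  sol_with <- solve_tree(tree, config)
  pruned <- vessel_tree(tree$main_vessel, tree$inlet_pressure_Pa,
                        tree$main_outlet, stenoses = tree$stenoses)
  sol_without <- solve_tree(pruned, config)
  structure(list(ffr_with = sol_with$distal_FFR,
                 ffr_without = sol_without$distal_FFR,
                 delta_ffr = sol_without$distal_FFR - sol_with$distal_FFR,
                 inlet_flow_with = sol_with$inlet_flow,
                 inlet_flow_without = sol_without$inlet_flow,
                 flows_with = sol_with$section_flows,
                 flows_without = rep(sol_without$inlet_flow,
                                     length(sol_with$section_flows)),
                 solution_with = sol_with,
                 solution_without = sol_without),
            class = "branch_comparison")
}

#' @export
print.branch_comparison <- function(x, ...) {
  cat(sprintf(paste0("<branch_comparison> FFR with branches %.4f, without ",
                     "%.4f (delta %.4f); inlet flow %.1f vs %.1f mL/min\n"),
              x$ffr_with, x$ffr_without, x$delta_ffr,
              m3_s_to_mL_min(x$inlet_flow_with),
              m3_s_to_mL_min(x$inlet_flow_without)))
  invisible(x)
}

#' Murray's-law flow distribution along the main vessel
#'
#' Distributes the inlet flow junction by junction according to Murray's law
#' (Q proportional to d^3): at each ostium the incoming flow splits between
#' the continuing main vessel and the branch in proportion to the cubes of
#' the local main-vessel diameter (taken from the healthy profile at the
#' ostium) and the branch ostium diameter.
#'
#' @param tree a [vessel_tree()].
#' @param inlet_flow total inflow to distribute (m^3/s), > 0.
#' @return numeric vector of main-vessel section flows (m^3/s), one per
#'   inter-junction section; the discarded branch shares account for the
#'   difference between consecutive entries.
#' @export
murray_flow_profile <- function(tree, inlet_flow) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (inlet_flow <= 0) stop_domain("inlet flow must be positive")
  q <- inlet_flow
  flows <- q
  for (sb in tree$side_branches) {
    d_main <- profile_diameter(tree$main_vessel, sb$attach_m)
    if (d_main <= 0 || sb$diameter_m <= 0)
      stop_domain("zero diameter at a junction")
    share_main <- d_main^3 / (d_main^3 + sb$diameter_m^3)
    q <- q * share_main
    flows <- c(flows, q)
  }
  flows
}

#' Mean relative discrepancy between two section flow profiles
#'
#' Diagnostic for how far a solved flow profile deviates from the
#' morphometric (Murray) distribution: mean over sections of
#' (murray - solver) / murray.
#'
#' @param solver_flows,murray_flows equal-length numeric vectors of section
#'   flows.
#' @return mean relative difference (dimensionless; positive when the solver
#'   runs below the Murray profile).
#' @export
flow_profile_discrepancy <- function(solver_flows, murray_flows) {
  if (length(solver_flows) != length(murray_flows))
    stop_domain("flow profiles must have equal length")
  mean((murray_flows - solver_flows) / murray_flows)
}
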