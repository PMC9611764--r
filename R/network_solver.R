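#' Solver configuration
#'
#' @param neglect_healthy_resistance if `TRUE`, healthy (non-stenosed)
#'   main-vessel segments carry zero resistance — the circuit idealization in
#'   which only stenoses and distal microvascular beds drop pressure. Default
#'   `FALSE`: healthy segments get their Poiseuille resistance.
#' @param mu viscosity for healthy-segment resistances (Pa.s).
#' @param quad_step_m quadrature step for viscous integrals (m).
#' @param tol relative flow-change convergence tolerance of the fixed-point
#'   iteration.
#' @param max_iter iteration cap.
#' @param damping under-relaxation factor in (0, 1] applied to flow updates.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(neglect_healthy_resistance = FALSE, mu = 0.0035,
                          quad_step_m = 5e-5, tol = 1e-10, max_iter = 200L,
                          damping = 0.5) {
  if (tol <= 0 || max_iter < 1 || damping <= 0 || damping > 1)
    stop_domain("invalid solver tolerances")
  structure(list(neglect_healthy_resistance = neglect_healthy_resistance,
                 mu = mu, quad_step_m = quad_step_m, tol = tol,
                 max_iter = as.integer(max_iter), damping = damping),
            class = "solver_config")
}

#' Closed-form circuit model for the idealized configurations
#'
#' The electrical analogue of a single stenosed vessel with at most one side
#' branch: inlet pressure V drives flow through the stenosis resistance R(q)
#' into the distal microvascular resistance R1; a side branch with distal
#' resistance R2 sits either proximal (upstream) or distal (downstream) of
#' the stenosis, or is absent. Healthy-segment resistance is neglected.
#'
#' @param V_Pa inlet pressure (Pa), > 0.
#' @param stenosis a [stenosis_model()].
#' @param R1 distal resistance of the main vessel (Pa.s.m^-3), > 0.
#' @param R2 distal resistance of the side branch, or `NULL` when
#'   `branch_location = "none"`.
#' @param branch_location one of `"none"`, `"upstream"`, `"downstream"`.
#' @return an object of class `circuit_model`.
#' @export
circuit_model <- function(V_Pa, stenosis, R1, R2 = NULL,
                          branch_location = c("none", "upstream",
                                              "downstream")) {
  branch_location <- match.arg(branch_location)
  stopifnot(inherits(stenosis, "stenosis_model"))
  if (V_Pa <= 0 || R1 <= 0) stop_domain("V and R1 must be positive")
  if (branch_location != "none") {
    if (is.null(R2) || R2 <= 0)
      stop_domain("a branch configuration needs R2 > 0")
  } else R2 <- NULL
  structure(list(V_Pa = V_Pa, stenosis = stenosis, R1 = R1, R2 = R2,
                 branch_location = branch_location),
            class = "circuit_model")
}

#' Total parallel resistance of main and branch distal beds
#'
#' @param R1,R2 distal resistances (Pa.s.m^-3), > 0.
#' @return Rt = R1 R2 / (R1 + R2).
#' @export
total_parallel_Rt <- function(R1, R2) parallel_resistance(R1, R2)

# positive root of C2 q^2 + (C1 + R) q - V = 0
stenosis_flow_root <- function(sten, R, V) {
  a <- sten$C2; b <- sten$C1 + R
  if (a == 0) return(V / b)
  disc <- b^2 + 4 * a * V
  # numerically stable form of the positive quadratic root
  2 * V / (b + sqrt(disc))
}

#' Solve an idealized circuit in closed form
#'
#' The stenosis flow is the positive root of C2 q^2 + (C1 + R_eff) q = V,
#' where R_eff is R1 (no branch, upstream branch) or Rt = R1 || R2
#' (downstream branch). The distal FFR is R_eff q / V = R_eff /
#' (R_eff + R(q)). An upstream branch draws V / R2 independently of the
#' stenosis and therefore leaves the FFR untouched; a downstream branch
#' lowers R_eff below R1 and strictly lowers the FFR.
#'
#' @param model a [circuit_model()].
#' @return a list with elements `FFR`, `q_stenosis`, `inlet_flow`,
#'   `main_outlet_flow`, `branch_flow` (0 when no branch), `distal_pressure_Pa`
#'   and `R_eff` (all SI).
#' @export
solve_circuit_closed_form <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  V <- model$V_Pa
  R_eff <- switch(model$branch_location,
                  none = model$R1,
                  upstream = model$R1,
                  downstream = total_parallel_Rt(model$R1, model$R2))
  q <- stenosis_flow_root(model$stenosis, R_eff, V)
  if (!is.finite(q) || q <= 0)
    stop("internal error: no positive stenosis flow root")
  V1 <- R_eff * q
  ffr <- V1 / V
  main_q <- V1 / model$R1
  branch_q <- switch(model$branch_location,
                     none = 0,
                     upstream = V / model$R2,
                     downstream = V1 / model$R2)
  list(FFR = ffr,
       q_stenosis = q,
       inlet_flow = if (model$branch_location == "upstream") q + branch_q
                    else q,
       main_outlet_flow = main_q,
       branch_flow = branch_q,
       distal_pressure_Pa = V1,
       R_eff = R_eff)
}

# --- full-tree ladder solver ----------------------------------------------

# Decompose the tree into a ladder: nodes at the inlet, at each branch ostium
# and at the distal end of the main vessel; sections between consecutive
# nodes carry a linear healthy resistance plus the stenoses whose throats lie
# inside them.
build_ladder <- function(tree, config) {
  ext <- profile_extent(tree$main_vessel)
  attach_s <- vapply(tree$side_branches, `[[`, 0, "attach_m")
  nodes <- c(ext[1], attach_s, ext[2])
  if (any(diff(nodes) <= 0))
    stop_domain("branch ostia must lie strictly inside the main vessel and be distinct")
  n_sec <- length(nodes) - 1L
  sections <- vector("list", n_sec)
  for (k in seq_len(n_sec)) {
    from <- nodes[k]; to <- nodes[k + 1]
    in_sec <- Filter(function(st) st$center_m >= from && st$center_m < to,
                     tree$stenoses)
    for (st in in_sec)
      if (st$center_m - st$length_m / 2 < from - 1e-12 ||
          st$center_m + st$length_m / 2 > to + 1e-12)
        stop_domain("a stenosis may not straddle a branch ostium")
    models <- lapply(in_sec, function(st)
      default_coefficients(tree$main_vessel, st, mu = config$mu,
                           step_m = config$quad_step_m))
    R_lin <- 0
    if (!config$neglect_healthy_resistance) {
      # healthy remainder of the section: total minus the stenosed intervals,
      # whose viscous part is already inside each C1
      bounds <- sort(unlist(lapply(in_sec, function(st)
        c(max(from, st$center_m - st$length_m / 2),
          min(to, st$center_m + st$length_m / 2)))))
      cuts <- c(from, bounds, to)
      for (i in seq(1, length(cuts) - 1, by = 2)) {
        a <- cuts[i]; b <- cuts[i + 1]
        if (b - a > 1e-12)
          R_lin <- R_lin + segment_viscous_resistance(
            tree$main_vessel, config$mu, a, b, step_m = config$quad_step_m)
      }
    }
    sections[[k]] <- list(from = from, to = to, R_lin = R_lin,
                          stenoses = models)
  }
  list(nodes = nodes, sections = sections,
       branch_R = vapply(tree$side_branches,
                         function(b) b$outlet$resistance_Pa_s_m3, 0),
       R_main = tree$main_outlet$resistance_Pa_s_m3)
}

section_resistance <- function(sec, q) {
  r <- sec$R_lin
  for (m in sec$stenoses) r <- r + stenosis_flow_resistance(m, q)
  r
}

# Exact solve of the ladder with frozen section resistances Rs: backward
# series/parallel reduction, then a forward pressure/flow sweep.
ladder_linear_solve <- function(ladder, Rs, P_in) {
  n <- length(Rs)
  R_eff <- numeric(n + 1)           # Thevenin resistance to ground at node k
  R_eff[n + 1] <- ladder$R_main
  R_in <- numeric(n)                # looking distally into section k
  for (k in n:1) {
    R_in[k] <- Rs[k] + R_eff[k + 1]
    R_eff[k] <- if (k >= 2) parallel_resistance(ladder$branch_R[k - 1], R_in[k])
                else R_in[k]
  }
  P <- numeric(n + 1); P[1] <- P_in
  q_sec <- numeric(n); q_br <- numeric(max(n - 1, 0))
  for (k in seq_len(n)) {
    q_sec[k] <- P[k] / R_in[k]
    P[k + 1] <- P[k] - q_sec[k] * Rs[k]
    if (k < n) q_br[k] <- P[k + 1] / ladder$branch_R[k]
  }
  list(P = P, q_sec = q_sec, q_br = q_br)
}

#' Solve steady pressures and flows in a vessel tree
#'
#' Damped fixed-point iteration on the flow-dependent stenosis resistances:
#' R(q) is frozen at the current section flows, the resulting linear
#' resistive ladder is solved exactly by series/parallel reduction, and the
#' flows are under-relaxed until the largest relative flow change falls below
#' the tolerance.
#'
#' @param tree a [vessel_tree()].
#' @param config a [solver_config()].
#' @return an object of class `network_solution`: `node_s_m` and
#'   `node_pressures_Pa` at the inlet, each ostium and the distal main node;
#'   `node_FFR`; `section_flows` (m^3/s, one per inter-node section);
#'   `branch_flows`; `inlet_flow`; `main_outlet_flow`; `converged`,
#'   `iterations` and `residual` (largest relative flow-conservation error).
#' @export
solve_tree <- function(tree, config = solver_config()) {
  stopifnot(inherits(tree, "vessel_tree"))
  ladder <- build_ladder(tree, config)
  n <- length(ladder$sections)
  q <- rep(0, n)
  converged <- FALSE
  history <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    Rs <- vapply(seq_len(n), function(k)
      section_resistance(ladder$sections[[k]], q[k]), 0)
    sol <- ladder_linear_solve(ladder, Rs, tree$inlet_pressure_Pa)
    if (any(sol$q_sec < 0) || any(sol$P < -1e-9))
      stop_domain("flow reversal encountered; the steady tree model assumes inlet-to-outlet flow")
    delta <- max(abs(sol$q_sec - q) / pmax(abs(sol$q_sec), 1e-300))
    history <- c(history, delta)
    q <- q + config$damping * (sol$q_sec - q)
    if (delta < config$tol) { converged <- TRUE; break }
  }
  # final consistent solve at the converged resistances
  Rs <- vapply(seq_len(n), function(k)
    section_resistance(ladder$sections[[k]], q[k]), 0)
  sol <- ladder_linear_solve(ladder, Rs, tree$inlet_pressure_Pa)
  if (!converged) {
    e <- simpleError("tree solver did not converge")
    e$iteration_history <- history
    stop(e)
  }
  cons <- 0
  if (n >= 2)
    cons <- max(abs(sol$q_sec[-n] - sol$q_sec[-1] - sol$q_br) /
                  abs(sol$q_sec[1]))
  structure(list(node_s_m = ladder$nodes,
                 node_pressures_Pa = sol$P,
                 node_FFR = sol$P / tree$inlet_pressure_Pa,
                 section_flows = sol$q_sec,
                 branch_flows = sol$q_br,
                 inlet_flow = sol$q_sec[1],
                 main_outlet_flow = sol$q_sec[n],
                 distal_FFR = sol$P[n + 1] / tree$inlet_pressure_Pa,
                 section_resistances = Rs,
                 converged = converged,
                 iterations = it,
                 residual = cons,
                 tree = tree,
                 config = config),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf(paste0("<network_solution> distal FFR %.4f, inlet flow ",
                     "%.2f mL/min, %d iterations, residual %.2e\n"),
              x$distal_FFR, m3_s_to_mL_min(x$inlet_flow), x$iterations,
              x$residual))
  invisible(x)
}

#' Export a network solution as data frames
#'
#' @param solution a [solve_tree()] result.
#' @return a list of two data frames: `nodes` (node_id, s_mm, pressure_mmHg,
#'   FFR) and `edges` (edge_id, flow_mL_min).
#' @export
solution_tables <- function(solution) {
  stopifnot(inherits(solution, "network_solution"))
  n <- length(solution$section_flows)
  node_id <- c("inlet",
               if (n >= 2) paste0("junction_", seq_len(n - 1)),
               "main_distal")
  nodes <- data.frame(node_id = node_id,
                      s_mm = m_to_mm(solution$node_s_m),
                      pressure_mmHg = Pa_to_mmHg(solution$node_pressures_Pa),
                      FFR = solution$node_FFR)
  edges <- data.frame(
    edge_id = c(paste0("section_", seq_len(n)),
                if (n >= 2) paste0("branch_", seq_len(n - 1)),
                "main_outlet"),
    flow_mL_min = m3_s_to_mL_min(c(solution$section_flows,
                                   solution$branch_flows,
                                   solution$main_outlet_flow)))
  list(nodes = nodes, edges = edges)
}

#' Calibrate the distal main-vessel resistance to a measured FFR
#'
#' Monotone bisection on log10(R1): the distal FFR increases with the distal
#' microvascular resistance, so the R1 reproducing a measured FFR is found by
#' root bracketing on \[1e6, 1e16\] Pa.s.m^-3. Side-branch resistances stay
#' fixed — the workflow used when a pressure-wire measurement anchors the
#' main-vessel bed while branch beds come from the structured tree.
#'
#' @param tree a [vessel_tree()]; its `main_outlet` resistance is the
#'   quantity being calibrated (the stored value is ignored).
#' @param measured_FFR target distal FFR in (0, 1).
#' @param config a [solver_config()].
#' @param tol_FFR absolute FFR tolerance of the root find.
#' @return the calibrated resistance (Pa.s.m^-3).
#' @export
calibrate_distal_resistance <- function(tree, measured_FFR,
                                        config = solver_config(),
                                        tol_FFR = 1e-6) {
  if (measured_FFR <= 0 || measured_FFR >= 1)
    stop_domain("measured FFR must lie strictly between 0 and 1")
  ffr_at <- function(log10R) {
    tr <- tree
    tr$main_outlet <- outlet_spec(10^log10R, tree$main_outlet$label)
    solve_tree(tr, config)$distal_FFR
  }
  lo <- 6; hi <- 16
  f_lo <- ffr_at(lo) - measured_FFR
  f_hi <- ffr_at(hi) - measured_FFR
  if (f_lo > 0 || f_hi < 0)
    stop_domain("calibration target unreachable within bracket [1e6, 1e16]")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- ffr_at(mid) - measured_FFR
    if (abs(f_mid) < tol_FFR) return(10^mid)
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  stop_domain("calibration did not converge")
}
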