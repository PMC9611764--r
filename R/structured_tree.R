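#' Structured-tree microvascular model parameters
#'
#' The fractal binary tree used to turn an outlet diameter into a distal
#' microvascular resistance. Each vessel of diameter d has length gamma * d
#' and bifurcates into daughters of diameters alpha * d and beta * d;
#' branching terminates when the diameter falls below `d_min_m` (the
#' arteriolar scale). Series/parallel reduction of the Poiseuille resistances
#' of all branches yields the outlet resistance. Under hyperemia the total is
#' scaled by `hyperemia_factor`, the measured resistance reduction with
#' adenosine at 140 ug/kg/min.
#'
#' @param alpha larger daughter diameter scale, in (0, 1).
#' @param beta smaller daughter diameter scale, 0 < beta <= alpha.
#' @param gamma length-to-diameter ratio, > 0.
#' @param d_min_m terminal (arteriolar) diameter (m), > 0.
#' @param mu viscosity used in the branch resistances (Pa.s). The default is
#'   the infinite-shear Carreau asymptote, the conventional choice for a
#'   resistance-only tree.
#' @param hyperemia_factor multiplicative resistance scale in (0, 1].
#' @return an object of class `structured_tree_params`.
#' @export
structured_tree_params <- function(alpha = 0.9, beta = 0.5, gamma = 25,
                                   d_min_m = 50e-6, mu = 0.0035,
                                   hyperemia_factor = 0.24) {
  if (!(beta > 0 && beta <= alpha && alpha < 1))
    stop_domain("need 0 < beta <= alpha < 1")
  if (gamma <= 0 || d_min_m <= 0 || mu <= 0)
    stop_domain("gamma, d_min_m and mu must be positive")
  if (hyperemia_factor <= 0 || hyperemia_factor > 1)
    stop_domain("hyperemia_factor must lie in (0, 1]")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 d_min_m = d_min_m, mu = mu,
                 hyperemia_factor = hyperemia_factor),
            class = "structured_tree_params")
}

#' Resistance of one structured-tree branch segment
#'
#' Poiseuille resistance of a branch whose length is gamma times its
#' diameter: R = 128 mu gamma / (pi d^3).
#'
#' @param d branch diameter (m), > 0; vectorized.
#' @param params a [structured_tree_params()].
#' @return hydraulic resistance (Pa.s.m^-3).
#' @export
tree_segment_resistance <- function(d, params = structured_tree_params()) {
  if (any(d <= 0)) stop_domain("diameter must be positive")
  128 * params$mu * params$gamma / (pi * d^3)
}

#' Parallel combination of two resistances
#'
#' @param r1,r2 resistances, > 0.
#' @return r1 * r2 / (r1 + r2), always below min(r1, r2).
#' @export
parallel_resistance <- function(r1, r2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop_domain("resistances must be positive")
  r1 * r2 / (r1 + r2)
}

#' Total resistance of a structured tree
#'
#' Series/parallel reduction of the whole fractal tree rooted at diameter
#' `d_root`: R(d) = R_seg(d) for a leaf (d < d_min), otherwise
#' R_seg(d) + parallel(R(alpha d), R(beta d)). Every reachable diameter is
#' d_root * alpha^i * beta^j, so the recursion is memoized on the integer
#' exponent pair (i, j); the alpha-chain from 3 mm to 50 um is ~39 levels
#' deep and naive recursion would need ~2^39 calls, while distinct (i, j)
#' states number only in the hundreds.
#'
#' @param d_root root diameter (m), > 0.
#' @param params a [structured_tree_params()].
#' @param hyperemia if `TRUE` (default) the total is multiplied by
#'   `params$hyperemia_factor` to represent the hyperemic state in which FFR
#'   is defined.
#' @return hydraulic resistance (Pa.s.m^-3).
#' @examples
#' tree_resistance(3e-3)              # hyperemic CMVR of a 3 mm outlet
#' tree_resistance(3e-3, hyperemia = FALSE)
#' @export
tree_resistance <- function(d_root, params = structured_tree_params(),
                            hyperemia = TRUE) {
  if (!is.finite(d_root) || d_root <= 0)
    stop_domain("root diameter must be positive")
  memo <- new.env(parent = emptyenv())
  la <- log(params$alpha); lb <- log(params$beta)
  rec <- function(i, j) {
    key <- paste(i, j, sep = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    d <- d_root * exp(i * la + j * lb)
    r <- tree_segment_resistance(d, params)
    if (d >= params$d_min_m)
      r <- r + parallel_resistance(rec(i + 1, j), rec(i, j + 1))
    memo[[key]] <- r
    r
  }
  r <- rec(0L, 0L)
  if (hyperemia) r <- r * params$hyperemia_factor
  r
}

#' Murray-law distal resistance scaling
#'
#' Under Murray's law the distal microvascular resistance of a vessel scales
#' with the inverse cube of its diameter, R ~ d^-3. Given a reference vessel
#' with known resistance, this returns the resistance of a vessel of another
#' diameter: R = reference_R * (reference_d / d)^3.
#'
#' @param d diameter of the vessel of interest (m), > 0.
#' @param reference_d reference diameter (m), > 0.
#' @param reference_R reference resistance (Pa.s.m^-3), > 0.
#' @return scaled resistance (Pa.s.m^-3).
#' @export
murray_distal_resistance <- function(d, reference_d, reference_R) {
  if (any(d <= 0) || any(reference_d <= 0) || any(reference_R <= 0))
    stop_domain("all inputs must be positive")
  reference_R * (reference_d / d)^3
}
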