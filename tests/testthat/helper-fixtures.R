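# Independent oracles and shared fixtures for the suite.

# Plain unmemoized structured-tree recursion; tractable only for small roots.
naive_tree_resistance <- function(d, params) {
  r <- 128 * params$mu * params$gamma / (pi * d^3)
  if (d < params$d_min_m) return(r)
  r1 <- naive_tree_resistance(params$alpha * d, params)
  r2 <- naive_tree_resistance(params$beta * d, params)
  r + r1 * r2 / (r1 + r2)
}

# Fine-step trapezoid quadrature of the viscous resistance density,
# independent of the package's anchored-grid quadrature.
fine_viscous_integral <- function(profile, mu, from, to, stenoses = NULL,
                                  step = 1e-6) {
  g <- seq(from, to, length.out = max(2, ceiling((to - from) / step) + 1))
  d <- profile_diameter(profile, g, stenoses)
  f <- 128 * mu / (pi * d^4)
  sum(diff(g) * (f[-length(f)] + f[-1]) / 2)
}

# Closed-form circuit equivalent of an idealized fixture tree (healthy
# segment resistance neglected), for oracle-equivalence checks.
circuit_from_fixture <- function(tree, location) {
  sten <- default_coefficients(tree$main_vessel, tree$stenoses[[1]])
  R2 <- if (length(tree$side_branches))
    tree$side_branches[[1]]$outlet$resistance_Pa_s_m3 else NULL
  circuit_model(tree$inlet_pressure_Pa, sten,
                R1 = tree$main_outlet$resistance_Pa_s_m3,
                R2 = R2, branch_location = location)
}

neglect_cfg <- function() solver_config(neglect_healthy_resistance = TRUE)
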