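#' Default run configuration
#'
#' The full parameter set of a pipeline run, as a nested list mirroring the
#' YAML config file layout: blood physiology (density, Carreau rheology, the
#' effective viscosity used in resistances), structured-tree microvascular
#' parameters, stenosis defaults, and solver tolerances.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    physiology = list(rho_kg_m3 = 1050,
                      mu_Pa_s = 0.0035,
                      carreau = list(mu_inf = 0.0035, mu_0 = 0.25,
                                     lambda_s = 25, n_index = 0.25)),
    structured_tree = list(alpha = 0.9, beta = 0.5, gamma = 25,
                           d_min_um = 50, mu_Pa_s = 0.0035,
                           hyperemia_factor = 0.24),
    stenosis = list(Kt = 1.52, rho_kg_m3 = 1050,
                    neglect_healthy_resistance = FALSE),
    solver = list(tol = 1e-10, max_iter = 200, damping = 0.5,
                  quad_step_mm = 0.05)),
    class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Starts from [default_run_config()], overlays a YAML file if given, then
#' overlays explicit overrides (overrides win).
#'
#' @param path optional YAML file path.
#' @param overrides optional nested list of final overrides.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop_domain("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config a `run_config` list.
#' @return `as_solver_config()`: the [solver_config()] implied by a run
#'   config; `as_tree_params()`: the [structured_tree_params()].
#' @export
as_solver_config <- function(config) {
  solver_config(
    neglect_healthy_resistance = config$stenosis$neglect_healthy_resistance,
    mu = config$physiology$mu_Pa_s,
    quad_step_m = mm_to_m(config$solver$quad_step_mm),
    tol = config$solver$tol,
    max_iter = config$solver$max_iter,
    damping = config$solver$damping)
}

#' @rdname load_run_config
#' @export
as_tree_params <- function(config) {
  st <- config$structured_tree
  structured_tree_params(alpha = st$alpha, beta = st$beta, gamma = st$gamma,
                         d_min_m = st$d_min_um * 1e-6, mu = st$mu_Pa_s,
                         hyperemia_factor = st$hyperemia_factor)
}
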