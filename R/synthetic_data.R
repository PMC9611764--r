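#' Idealized stenosed-artery fixtures
#'
#' Builds the three canonical single-vessel benchmark geometries: a straight
#' 75 mm main vessel of 3 mm diameter with one 10 mm-long stenosis of 20%
#' minimum lumen area at mid-vessel, and optionally one 2.5 mm side branch
#' attached 25 mm from the stenosis throat, proximal (`model2_upstream`) or
#' distal (`model3_downstream`) of it, at a 75 degree angle. Inlet pressure
#' is 90 mmHg.
#'
#' @param variant `"model1_no_branch"`, `"model2_upstream"` or
#'   `"model3_downstream"`.
#' @param outlet_policy `"structured_tree"` (default): each outlet gets the
#'   hyperemic structured-tree resistance for its diameter; or `"explicit"`,
#'   using `R_main` / `R_branch`.
#' @param R_main,R_branch explicit outlet resistances (Pa.s.m^-3), used when
#'   `outlet_policy = "explicit"`.
#' @param tree_params a [structured_tree_params()].
#' @return a [vessel_tree()].
#' @examples
#' make_idealized("model3_downstream")
#' @export
make_idealized <- function(variant = c("model1_no_branch", "model2_upstream",
                                       "model3_downstream"),
                           outlet_policy = c("structured_tree", "explicit"),
                           R_main = NULL, R_branch = NULL,
                           tree_params = structured_tree_params()) {
  variant <- match.arg(variant)
  outlet_policy <- match.arg(outlet_policy)
  len <- mm_to_m(75); d_main <- mm_to_m(3)
  sten_center <- mm_to_m(37.5)
  branch_d <- mm_to_m(2.5)
  offset <- mm_to_m(25)
  profile <- lumen_profile(c(0, len), c(d_main, d_main))
  sten <- stenosis_spec(sten_center, mm_to_m(10), 0.2)
  if (outlet_policy == "structured_tree") {
    R_main <- tree_resistance(d_main, tree_params)
    R_branch <- tree_resistance(branch_d, tree_params)
  } else if (is.null(R_main) ||
             (variant != "model1_no_branch" && is.null(R_branch)))
    stop_domain("explicit outlet policy requires R_main (and R_branch)")
  branches <- switch(variant,
    model1_no_branch = list(),
    model2_upstream = list(side_branch_spec(
      sten_center - offset, branch_d,
      outlet_spec(R_branch, "branch_outlet"), angle_deg = 75)),
    model3_downstream = list(side_branch_spec(
      sten_center + offset, branch_d,
      outlet_spec(R_branch, "branch_outlet"), angle_deg = 75)))
  vessel_tree(profile, mmHg_to_Pa(90),
              outlet_spec(R_main, "main_outlet"),
              stenoses = list(sten), side_branches = branches)
}

#' Configuration for randomized patient-like trees
#'
#' Controls the generator that emulates an OCT-pullback-derived vessel: a
#' lumen-area profile sampled at the imaging frame spacing (0.2 mm, the
#' 36 mm/s pullback at 180 frames/s) with multiplicative segmentation-like
#' area noise, a tapering main vessel, randomized side-branch layout and one
#' or more stenoses.
#'
#' @param seed mandatory integer seed; all draws come from one generator.
#' @param preset `"patient1_like"` (stenosis distal to most branches, the
#'   layout where branch flow barely moves the FFR) or `"patient2_like"`
#'   (focal proximal stenosis with the branches downstream, the layout where
#'   neglecting branches overestimates the FFR).
#' @param n_branches number of side branches.
#' @param branch_diameter_range_m branch ostium diameter range (m); branches
#'   below 0.5 mm are never generated, mirroring how sub-resolution branches
#'   are ignored during segmentation.
#' @param n_stenoses number of stenoses.
#' @param severity_range minimum-area ratio range (fraction of healthy area).
#' @param stenosis_length_m lesion length (m).
#' @param main_length_m main-vessel length (m).
#' @param main_diameter_m proximal main-vessel diameter (m).
#' @param taper distal-to-proximal diameter ratio of the healthy vessel.
#' @param frame_spacing_m lumen-profile sample spacing (m).
#' @param area_noise_sd relative SD of multiplicative Gaussian area noise,
#'   truncated at +/- 3 SD.
#' @return a list of class `synthetic_tree_config`.
#' @export
synthetic_tree_config <- function(seed,
                                  preset = c("patient1_like",
                                             "patient2_like"),
                                  n_branches = 3L,
                                  branch_diameter_range_m = c(1e-3, 2.5e-3),
                                  n_stenoses = 1L,
                                  severity_range = c(0.2, 0.5),
                                  stenosis_length_m = 10e-3,
                                  main_length_m = 75e-3,
                                  main_diameter_m = 3e-3,
                                  taper = 0.85,
                                  frame_spacing_m = 0.2e-3,
                                  area_noise_sd = 0.02) {
  preset <- match.arg(preset)
  if (missing(seed) || !is.finite(seed))
    stop_domain("a seed is mandatory for reproducible generation")
  if (any(branch_diameter_range_m < 0.5e-3))
    stop_domain("branches below 0.5 mm are not generated")
  if (diff(branch_diameter_range_m) < 0 || diff(severity_range) < 0)
    stop_domain("ranges must be ordered")
  if (any(severity_range <= 0) || any(severity_range >= 1))
    stop_domain("severity range must lie in (0, 1)")
  if (frame_spacing_m <= 0 || area_noise_sd < 0)
    stop_domain("frame spacing must be positive and noise SD non-negative")
  structure(list(seed = as.integer(seed), preset = preset,
                 n_branches = as.integer(n_branches),
                 branch_diameter_range_m = branch_diameter_range_m,
                 n_stenoses = as.integer(n_stenoses),
                 severity_range = severity_range,
                 stenosis_length_m = stenosis_length_m,
                 main_length_m = main_length_m,
                 main_diameter_m = main_diameter_m,
                 taper = taper,
                 frame_spacing_m = frame_spacing_m,
                 area_noise_sd = area_noise_sd),
            class = "synthetic_tree_config")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rtruncnorm3 <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -3 * sd), 3 * sd)
}

#' Generate a randomized patient-like vessel tree
#'
#' Reproducible given the seed: emits a lumen profile sampled at the frame
#' spacing with truncated multiplicative area noise, places stenoses and
#' side branches according to the preset layout, and attaches hyperemic
#' structured-tree outlet resistances sized by local diameter.
#'
#' @param config a [synthetic_tree_config()].
#' @param tree_params a [structured_tree_params()] for the outlet beds.
#' @param max_retries layout retries before giving up when branches and
#'   stenoses cannot be placed without overlap.
#' @return a [vessel_tree()].
#' @export
make_patient_like <- function(config, tree_params = structured_tree_params(),
                              max_retries = 100L) {
  stopifnot(inherits(config, "synthetic_tree_config"))
  with_local_seed(config$seed, {
    L <- config$main_length_m
    s <- seq(0, L, by = config$frame_spacing_m)
    if (s[length(s)] < L) s <- c(s, L)
    d0 <- config$main_diameter_m * (1 + (config$taper - 1) * s / L)
    area <- pi * d0^2 / 4
    if (config$area_noise_sd > 0)
      area <- area * (1 + rtruncnorm3(length(area), config$area_noise_sd))
    profile <- lumen_profile(s, sqrt(4 * area / pi))

    # preset windows (fractions of vessel length): where lesions and ostia go
    win <- switch(config$preset,
      patient1_like = list(sten = c(0.65, 0.85), branch = c(0.08, 0.55)),
      patient2_like = list(sten = c(0.12, 0.28), branch = c(0.45, 0.92)))
    half <- config$stenosis_length_m / 2
    for (try in seq_len(max_retries)) {
      sten_c <- sort(stats::runif(config$n_stenoses,
                                  win$sten[1] * L, win$sten[2] * L))
      br_s <- sort(stats::runif(config$n_branches,
                                win$branch[1] * L, win$branch[2] * L))
      clear <- all(vapply(br_s, function(b)
        all(abs(b - sten_c) > half + 1e-3), TRUE)) &&
        (config$n_branches < 2 || all(diff(br_s) > 1e-3)) &&
        (config$n_stenoses < 2 || all(diff(sten_c) > config$stenosis_length_m))
      if (clear) break
      if (try == max_retries)
        stop_domain("could not place branches clear of stenoses after ",
                    max_retries, " retries")
    }
    sev <- stats::runif(config$n_stenoses, config$severity_range[1],
                        config$severity_range[2])
    br_d <- stats::runif(config$n_branches,
                         config$branch_diameter_range_m[1],
                         config$branch_diameter_range_m[2])
    stenoses <- lapply(seq_len(config$n_stenoses), function(i)
      stenosis_spec(sten_c[i], config$stenosis_length_m, sev[i]))
    branches <- lapply(seq_len(config$n_branches), function(i)
      side_branch_spec(br_s[i], br_d[i],
                       outlet_spec(tree_resistance(br_d[i], tree_params),
                                   paste0("branch_", i)),
                       angle_deg = stats::runif(1, 45, 90)))
    d_distal <- config$main_diameter_m * config$taper
    vessel_tree(profile, mmHg_to_Pa(90),
                outlet_spec(tree_resistance(d_distal, tree_params),
                            "main_outlet"),
                stenoses = stenoses, side_branches = branches)
  })
}
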