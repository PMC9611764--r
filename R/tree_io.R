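TREE_SCHEMA <- "ffrtree/1"

stop_validation <- function(pointer, ...) {
  stop(structure(class = c("ffrtree_validation_error", "error", "condition"),
                 list(message = paste0("at ", pointer, ": ", ...),
                      pointer = pointer, call = sys.call(-1))))
}

#' Write a vessel tree to JSON
#'
#' Serializes a [vessel_tree()] to the package's versioned JSON schema.
#' Lengths are stored in mm, pressures in mmHg, resistances in Pa.s.m^-3;
#' numbers are written at full precision so that generation with the same
#' seed yields byte-identical files.
#'
#' @param tree a [vessel_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  obj <- list(
    schema = TREE_SCHEMA,
    main_vessel = list(s_mm = m_to_mm(tree$main_vessel$arc_length_m),
                       d_mm = m_to_mm(tree$main_vessel$diameter_m)),
    inlet_pressure_mmHg = Pa_to_mmHg(tree$inlet_pressure_Pa),
    stenoses = lapply(tree$stenoses, function(st)
      list(center_mm = m_to_mm(st$center_m),
           length_mm = m_to_mm(st$length_m),
           area_ratio = st$area_ratio)),
    side_branches = lapply(tree$side_branches, function(sb)
      list(s_mm = m_to_mm(sb$attach_m),
           d_mm = m_to_mm(sb$diameter_m),
           angle_deg = sb$angle_deg,
           outlet = list(R = sb$outlet$resistance_Pa_s_m3,
                         units = "Pa.s/m3",
                         label = sb$outlet$label))),
    main_outlet = list(R = tree$main_outlet$resistance_Pa_s_m3,
                       units = "Pa.s/m3",
                       label = tree$main_outlet$label))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

need <- function(x, field, pointer) {
  if (is.null(x[[field]])) stop_validation(paste0(pointer, "/", field),
                                           "required field missing")
  x[[field]]
}

#' Read a vessel tree from JSON
#'
#' Validates the schema version and required fields; violations raise a
#' validation error naming the offending JSON pointer.
#'
#' @param path path to a file written by [write_tree()].
#' @return a [vessel_tree()].
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  schema <- need(obj, "schema", "")
  if (!identical(schema, TREE_SCHEMA))
    stop(structure(class = c("ffrtree_schema_error", "error", "condition"),
                   list(message = paste0("unsupported schema version: ",
                                         schema), call = NULL)))
  mv <- need(obj, "main_vessel", "")
  profile <- lumen_profile(mm_to_m(need(mv, "s_mm", "/main_vessel")),
                           mm_to_m(need(mv, "d_mm", "/main_vessel")))
  mo <- need(obj, "main_outlet", "")
  main_outlet <- outlet_spec(need(mo, "R", "/main_outlet"),
                             if (is.null(mo$label)) "main_outlet" else mo$label)
  stenoses <- lapply(seq_along(obj$stenoses), function(i) {
    st <- obj$stenoses[[i]]; ptr <- paste0("/stenoses/", i - 1)
    stenosis_spec(mm_to_m(need(st, "center_mm", ptr)),
                  mm_to_m(need(st, "length_mm", ptr)),
                  need(st, "area_ratio", ptr))
  })
  branches <- lapply(seq_along(obj$side_branches), function(i) {
    sb <- obj$side_branches[[i]]; ptr <- paste0("/side_branches/", i - 1)
    out <- need(sb, "outlet", ptr)
    side_branch_spec(mm_to_m(need(sb, "s_mm", ptr)),
                     mm_to_m(need(sb, "d_mm", ptr)),
                     outlet_spec(need(out, "R", paste0(ptr, "/outlet")),
                                 if (is.null(out$label)) "branch" else
                                   out$label),
                     angle_deg = if (is.null(sb$angle_deg)) NA_real_ else
                       sb$angle_deg)
  })
  vessel_tree(profile, mmHg_to_Pa(need(obj, "inlet_pressure_mmHg", "")),
              main_outlet, stenoses = stenoses, side_branches = branches)
}
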