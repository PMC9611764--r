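#' Unit conversions
#'
#' Internally all quantities are strict SI: metres, pascals, cubic metres per
#' second, and Pa.s.m^-3 for hydraulic resistance. Clinical units (mmHg,
#' mL/min, mm) appear only at input/output boundaries, through these helpers.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
MMHG_PA <- 133.322

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
mL_min_to_m3_s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
m3_s_to_mL_min <- function(x) x * 60 / 1e-6

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

stop_domain <- function(...) {
  stop(structure(class = c("ffrtree_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
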