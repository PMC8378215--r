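#' Unit conversions between table units and SI
#'
#' Nozzle catalogues and printing protocols quote lengths in mm, pressures in
#' kPa and flow rates in µL/s; all internal computation is SI (m, Pa, m³/s).
#' These helpers are exact inverses of each other.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
kpa_to_pa <- function(x) x * 1e3

#' @rdname units
#' @export
pa_to_kpa <- function(x) x * 1e-3

#' @rdname units
#' @export
uls_to_m3s <- function(x) x * 1e-9

#' @rdname units
#' @export
m3s_to_uls <- function(x) x * 1e9
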