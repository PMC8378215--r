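#' Parameterized print-nozzle geometry
#'
#' Two ubiquitous nozzle shapes are supported, both axisymmetric:
#' \describe{
#'   \item{blunted}{a wide cylindrical barrel of radius `r_big` and length
#'     `l_upper` contracting abruptly (90 degree shoulder) into a thin
#'     straight tube of radius `r_small` and length `l_lower`;}
#'   \item{conical}{a linear taper from `r_big` to `r_middle` over `l_upper`
#'     followed by a linear taper from `r_middle` down to the exit radius
#'     `r_small` over `l_lower`.}
#' }
#' Dimensions are given in mm (catalogue convention) and stored internally in
#' metres. The flow axis runs from z = 0 (inlet) to z = l_upper + l_lower
#' (outlet).
#'
#' @param r_small exit radius (mm).
#' @param r_big entrance radius (mm).
#' @param r_middle intermediate radius (mm, conical only); the geometry is
#'   only valid when `r_small < r_middle < r_big`.
#' @param l_lower,l_upper lower/upper section lengths (mm).
#' @return an object of class `nozzle_geometry` (fields in metres).
#' @export
#' @examples
#' blunted_nozzle(r_small = 0.25, r_big = 3.5, l_lower = 6, l_upper = 4)
#' conical_nozzle(r_small = 0.227, r_middle = 1, r_big = 3.5,
#'                l_lower = 6, l_upper = 4)
blunted_nozzle <- function(r_small, r_big, l_lower, l_upper) {
  validate_geometry(new_nozzle("blunted", r_small = mm_to_m(r_small),
                               r_middle = NA_real_, r_big = mm_to_m(r_big),
                               l_lower = mm_to_m(l_lower),
                               l_upper = mm_to_m(l_upper)))
}

#' @rdname blunted_nozzle
#' @export
conical_nozzle <- function(r_small, r_middle, r_big, l_lower, l_upper) {
  validate_geometry(new_nozzle("conical", r_small = mm_to_m(r_small),
                               r_middle = mm_to_m(r_middle),
                               r_big = mm_to_m(r_big),
                               l_lower = mm_to_m(l_lower),
                               l_upper = mm_to_m(l_upper)))
}

new_nozzle <- function(shape, r_small, r_middle, r_big, l_lower, l_upper) {
  structure(
    list(shape = shape, r_small = r_small, r_middle = r_middle,
         r_big = r_big, l_lower = l_lower, l_upper = l_upper),
    class = "nozzle_geometry"
  )
}

#' Validate a nozzle geometry
#'
#' Checks positivity of all dimensions and the shape constraints:
#' `r_small < r_big` for blunted nozzles and the design-of-experiments
#' exclusion rule `r_small < r_middle < r_big` for conical nozzles (candidate
#' designs with the entrance radius not exceeding the intermediate radius are
#' invalid).
#'
#' @param geom a `nozzle_geometry`.
#' @return the geometry, unchanged, if valid; otherwise an error.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "nozzle_geometry"))
  dims <- c(r_small = geom$r_small, r_big = geom$r_big,
            l_lower = geom$l_lower, l_upper = geom$l_upper)
  if (geom$shape == "conical") dims <- c(dims, r_middle = geom$r_middle)
  bad <- !is.finite(dims) | dims <= 0
  if (any(bad))
    stop("nozzle dimensions must be positive and finite: ",
         paste(names(dims)[bad], collapse = ", "), call. = FALSE)
  if (geom$shape == "blunted") {
    if (geom$r_small >= geom$r_big)
      stop("blunted nozzle requires r_small < r_big", call. = FALSE)
  } else if (geom$shape == "conical") {
    if (geom$r_big <= geom$r_middle)
      stop("conical nozzle requires r_big > r_middle (design exclusion rule)",
           call. = FALSE)
    if (geom$r_middle <= geom$r_small)
      stop("conical nozzle requires r_middle > r_small", call. = FALSE)
  } else stop("unknown nozzle shape '", geom$shape, "'", call. = FALSE)
  geom
}

#' Total nozzle length (m)
#' @param geom a `nozzle_geometry`.
#' @export
nozzle_length <- function(geom) geom$l_upper + geom$l_lower

#' Wall radius profile R(z)
#'
#' The axial radius profile of the wetted wall. Conical: piecewise-linear and
#' continuous (`r_big` to `r_middle` over the upper section, `r_middle` to
#' `r_small` over the lower). Blunted: `r_big` for z < `l_upper`, `r_small`
#' from the shoulder on (single step discontinuity; the value at the shoulder
#' itself is `r_small`).
#'
#' @param geom a `nozzle_geometry`.
#' @param z axial coordinate(s) in metres, within `[0, nozzle_length(geom)]`.
#' @return wall radius in metres, vectorized over `z`.
#' @export
radius_profile <- function(geom, z) {
  stopifnot(inherits(geom, "nozzle_geometry"))
  L <- nozzle_length(geom)
  if (any(z < -1e-12 | z > L + 1e-12))
    stop("z outside nozzle domain [0, ", L, "]", call. = FALSE)
  z <- pmin(pmax(z, 0), L)
  if (geom$shape == "blunted") {
    ifelse(z < geom$l_upper, geom$r_big, geom$r_small)
  } else {
    upper <- geom$r_big + (geom$r_middle - geom$r_big) * z / geom$l_upper
    lower <- geom$r_middle +
      (geom$r_small - geom$r_middle) * (z - geom$l_upper) / geom$l_lower
    ifelse(z < geom$l_upper, upper, lower)
  }
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  mm <- function(v) sprintf("%.3g mm", m_to_mm(v))
  if (x$shape == "blunted") {
    cat(sprintf("<nozzle_geometry> blunted: Rs=%s Rb=%s Ll=%s Lu=%s\n",
                mm(x$r_small), mm(x$r_big), mm(x$l_lower), mm(x$l_upper)))
  } else {
    cat(sprintf("<nozzle_geometry> conical: Rs=%s Rm=%s Rb=%s Ll=%s Lu=%s\n",
                mm(x$r_small), mm(x$r_middle), mm(x$r_big),
                mm(x$l_lower), mm(x$l_upper)))
  }
  invisible(x)
}

#' Geometry as a one-row tibble (mm)
#' @param geom a `nozzle_geometry`.
#' @export
geometry_row <- function(geom) {
  tibble::tibble(
    shape = geom$shape,
    r_small_mm = m_to_mm(geom$r_small),
    r_middle_mm = m_to_mm(geom$r_middle),
    r_big_mm = m_to_mm(geom$r_big),
    l_lower_mm = m_to_mm(geom$l_lower),
    l_upper_mm = m_to_mm(geom$l_upper)
  )
}

#' Build a nozzle geometry from a row of design parameters in mm
#'
#' @param shape `"blunted"` or `"conical"`.
#' @param row a list/one-row data frame with `r_small_mm`, `r_big_mm`,
#'   `l_lower_mm`, `l_upper_mm` and (conical) `r_middle_mm`.
#' @export
geometry_from_row <- function(shape, row) {
  if (shape == "blunted") {
    blunted_nozzle(row$r_small_mm, row$r_big_mm, row$l_lower_mm, row$l_upper_mm)
  } else {
    conical_nozzle(row$r_small_mm, row$r_middle_mm, row$r_big_mm,
                   row$l_lower_mm, row$l_upper_mm)
  }
}
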