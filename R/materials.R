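#' Power-law (Ostwald-de Waele) bioink material
#'
#' A hydrogel bioink is modelled as an incompressible generalized-Newtonian
#' fluid with viscosity \eqn{\eta = K \dot\gamma^{n-1}} and shear stress
#' \eqn{\tau = \eta\dot\gamma = K \dot\gamma^{n}}, where \eqn{K} is the
#' consistency coefficient (Pa s^n) and \eqn{n} the flow-behaviour index
#' (shear-thinning for n < 1, Newtonian at n = 1).
#'
#' @param name label for the material.
#' @param rho density in kg/m^3 (> 0).
#' @param k consistency coefficient K in Pa s^n (> 0).
#' @param n power-law index (0 < n <= 1.2; values above ~0.8 behave
#'   practically Newtonian).
#' @param pressure_kpa optional default printing pressure in kPa.
#' @return an object of class `material`.
#' @export
#' @examples
#' material("Alginate", rho = 1000, k = 55.7, n = 0.335, pressure_kpa = 340)
material <- function(name, rho, k, n, pressure_kpa = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0)
    stop("material density `rho` must be a positive number (kg/m^3)", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("consistency coefficient `k` must be a positive number (Pa s^n)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n <= 0 || n > 1.2)
    stop("power-law index `n` must lie in (0, 1.2]", call. = FALSE)
  structure(
    list(name = name, rho = rho, k = k, n = n,
         pressure_kpa = as.numeric(pressure_kpa)),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho = %g kg/m^3, K = %g Pa.s^n, n = %g", x$name,
              x$rho, x$k, x$n))
  if (is.finite(x$pressure_kpa))
    cat(sprintf(", default printing pressure = %g kPa", x$pressure_kpa))
  cat("\n")
  invisible(x)
}

# Present-study rheology of the three reference hydrogels, with their common
# printing pressures. Density 1000 kg/m^3 throughout.
.builtin_materials <- list(
  PF127    = list(rho = 1000, k = 406,  n = 0.127, pressure_kpa = 200),
  Alginate = list(rho = 1000, k = 55.7, n = 0.335, pressure_kpa = 340),
  AlgGel   = list(rho = 1000, k = 13.3, n = 0.608, pressure_kpa = 80)
)

#' Built-in reference hydrogels
#'
#' Returns one of the three reference bioinks — Pluronic F127 (`"PF127"`,
#' strongly shear-thinning), 12% w/v alginate (`"Alginate"`) and
#' alginate-gelatin (`"AlgGel"`, close to Newtonian) — with its rheological
#' parameters and default printing pressure.
#'
#' @param name one of `"PF127"`, `"Alginate"`, `"AlgGel"`.
#' @return a [material()] object.
#' @export
#' @examples
#' builtin_material("Alginate")
builtin_material <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.builtin_materials))
    stop("unknown material '", paste(name, collapse = ","),
         "'; available: ", paste(names(.builtin_materials), collapse = ", "),
         call. = FALSE)
  p <- .builtin_materials[[name]]
  material(name, rho = p$rho, k = p$k, n = p$n, pressure_kpa = p$pressure_kpa)
}

#' Table of built-in bioinks
#'
#' @return a tibble with one row per built-in material.
#' @export
bioink_library <- function() {
  tibble::tibble(
    name = names(.builtin_materials),
    rho = purrr::map_dbl(.builtin_materials, "rho"),
    k = purrr::map_dbl(.builtin_materials, "k"),
    n = purrr::map_dbl(.builtin_materials, "n"),
    pressure_kpa = purrr::map_dbl(.builtin_materials, "pressure_kpa")
  )
}

#' Apparent viscosity and shear stress of a power-law fluid
#'
#' @param mat a [material()].
#' @param gamma_dot shear rate(s) in 1/s.
#' @param gamma_dot_min regularization floor on the shear rate; below it the
#'   viscosity is held constant (the power law diverges as the shear rate
#'   vanishes for n < 1).
#' @return viscosity in Pa s (`pl_viscosity`) or stress in Pa (`pl_stress`).
#' @export
pl_viscosity <- function(mat, gamma_dot, gamma_dot_min = 1e-3) {
  g <- pmax(gamma_dot, gamma_dot_min)
  mat$k * g^(mat$n - 1)
}

#' @rdname pl_viscosity
#' @export
pl_stress <- function(mat, gamma_dot, gamma_dot_min = 1e-3) {
  pl_viscosity(mat, gamma_dot, gamma_dot_min) * gamma_dot
}
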