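#' Closed-form power-law Poiseuille flow in a straight tube
#'
#' Fully developed laminar flow of a power-law fluid through a cylindrical
#' tube of radius R and length L under a pressure difference \eqn{\Delta p}:
#' \deqn{\tau_w = \frac{\Delta p\, R}{2 L}}
#' \deqn{V_{avg} = \frac{n}{3n+1}\left(\frac{\Delta p\, R}{2 K L}\right)^{1/n} R}
#' \deqn{Q = \pi R^2 V_{avg}}
#' These closed forms ignore entrance effects and any pressure drop outside
#' the tube; they serve as the literature baseline and as the oracle for the
#' numerical solvers.
#'
#' @param r tube radius in metres (> 0).
#' @param l tube length in metres (> 0).
#' @return a `pipe_spec` object.
#' @export
#' @examples
#' p <- pipe_spec(r = 0.05e-3, l = 6e-3)
#' pipe_wall_shear(kpa_to_pa(340), p)
pipe_spec <- function(r, l) {
  if (!is.numeric(r) || r <= 0 || !is.numeric(l) || l <= 0)
    stop("pipe radius and length must be positive", call. = FALSE)
  structure(list(r = r, l = l), class = "pipe_spec")
}

#' Wall shear stress in a straight tube
#'
#' \eqn{\tau_w = \Delta p R / (2L)}. Holds for any generalized-Newtonian fluid
#' in fully developed flow (pure force balance).
#'
#' @param delta_p pressure difference in Pa (>= 0).
#' @param pipe a [pipe_spec()].
#' @return wall shear stress in Pa.
#' @export
pipe_wall_shear <- function(delta_p, pipe) {
  if (any(delta_p < 0)) stop("delta_p must be non-negative", call. = FALSE)
  delta_p * pipe$r / (2 * pipe$l)
}

#' Mean velocity of power-law Poiseuille flow
#'
#' @param delta_p pressure difference in Pa (> 0).
#' @param pipe a [pipe_spec()].
#' @param mat a [material()].
#' @return average axial velocity in m/s.
#' @export
pipe_mean_velocity <- function(delta_p, pipe, mat) {
  if (mat$n <= 0) stop("power-law index must be positive", call. = FALSE)
  if (any(delta_p < 0)) stop("delta_p must be non-negative", call. = FALSE)
  mat$n / (3 * mat$n + 1) *
    (delta_p * pipe$r / (2 * mat$k * pipe$l))^(1 / mat$n) * pipe$r
}

#' Flow rate from mean velocity
#'
#' \eqn{Q = \pi R^2 V_{avg}}.
#'
#' @param pipe a [pipe_spec()].
#' @param v_avg average velocity in m/s (>= 0).
#' @return flow rate in m^3/s.
#' @export
pipe_flow_rate <- function(pipe, v_avg) {
  if (any(v_avg < 0)) stop("v_avg must be non-negative", call. = FALSE)
  pi * pipe$r^2 * v_avg
}

#' Fully developed power-law velocity profile
#'
#' \deqn{u(r) = \left(\frac{\Delta p}{2KL}\right)^{1/n} \frac{n}{n+1}
#'   \left(R^{(n+1)/n} - r^{(n+1)/n}\right)}
#' with no slip at the wall; its area average equals [pipe_mean_velocity()].
#'
#' @param r radial coordinate(s) in metres, `0 <= r <= R`.
#' @param delta_p pressure difference in Pa.
#' @param pipe a [pipe_spec()].
#' @param mat a [material()].
#' @return axial velocity in m/s, vectorized over `r`.
#' @export
pipe_velocity_profile <- function(r, delta_p, pipe, mat) {
  if (any(r < 0 | r > pipe$r * (1 + 1e-12)))
    stop("r outside tube cross-section [0, R]", call. = FALSE)
  m <- (mat$n + 1) / mat$n
  (delta_p / (2 * mat$k * pipe$l))^(1 / mat$n) * mat$n / (mat$n + 1) *
    (pipe$r^m - pmin(r, pipe$r)^m)
}

#' Pressure required for a target flow rate in a straight tube
#'
#' Exact closed-form inverse of the Poiseuille relations:
#' \deqn{\Delta p = \frac{2KL}{R}\left(\frac{(3n+1)Q}{n \pi R^3}\right)^{n}}
#'
#' @param q flow rate in m^3/s (> 0).
#' @param pipe a [pipe_spec()].
#' @param mat a [material()].
#' @return pressure difference in Pa.
#' @export
pipe_pressure_for_flow <- function(q, pipe, mat) {
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  2 * mat$k * pipe$l / pipe$r *
    ((3 * mat$n + 1) * q / (mat$n * pi * pipe$r^3))^mat$n
}

#' Fully developed wall shear stress at a given flow rate
#'
#' \eqn{\tau_w = K\left[(3n+1)Q/(n\pi R^3)\right]^n}; the local viscous kernel
#' used by the quasi-1D solver at every axial station.
#'
#' @param q flow rate in m^3/s.
#' @param r local wall radius in metres.
#' @param mat a [material()].
#' @return wall shear stress in Pa, vectorized over `r`.
#' @export
pipe_wall_shear_at_flow <- function(q, r, mat) {
  mat$k * ((3 * mat$n + 1) * q / (mat$n * pi * r^3))^mat$n
}
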