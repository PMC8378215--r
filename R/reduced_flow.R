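#' Options for the quasi-1D reduced nozzle solver
#'
#' @param n_stations number of axial stations per nozzle section (>= 10);
#'   stations never straddle the blunted shoulder.
#' @param alpha_mode kinetic-energy correction profile: `"fully_developed"`
#'   uses \eqn{\alpha(n)} of the fully developed power-law profile (see
#'   [alpha_energy()]), `"plug"` uses \eqn{\alpha = 1}.
#' @param include_upper include the upper nozzle section in the viscous
#'   integral (the upper-barrel pressure drop is small but not always
#'   negligible).
#' @param gamma_dot_min shear-rate regularization floor (1/s) used when
#'   averaging the exit viscosity.
#' @return a `reduced_options` list.
#' @export
reduced_options <- function(n_stations = 400,
                            alpha_mode = c("fully_developed", "plug"),
                            include_upper = TRUE,
                            gamma_dot_min = 1e-3) {
  if (n_stations < 10) stop("n_stations must be >= 10", call. = FALSE)
  list(n_stations = as.integer(n_stations),
       alpha_mode = match.arg(alpha_mode),
       include_upper = isTRUE(include_upper),
       gamma_dot_min = gamma_dot_min)
}

#' Kinetic-energy correction factor for a power-law profile
#'
#' The ratio of the true kinetic-energy flux to that of a plug profile with
#' the same mean velocity, i.e. the area average of \eqn{(u/\bar u)^3} for the
#' fully developed power-law profile:
#' \deqn{\alpha(n) = 2 c^3 \int_0^1 (1 - x^m)^3 x\,dx,\quad
#'   m = \frac{n+1}{n},\ c = \frac{3n+1}{n+1}.}
#' Evaluated in closed form; \eqn{\alpha(1) = 2} (parabolic profile) and
#' \eqn{\alpha \to 1} as \eqn{n \to 0} (plug flow).
#'
#' @param n power-law index (> 0).
#' @return dimensionless correction factor, vectorized over `n`.
#' @export
alpha_energy <- function(n) {
  if (any(n <= 0)) stop("power-law index must be positive", call. = FALSE)
  m <- (n + 1) / n
  c3 <- ((3 * n + 1) / (n + 1))^3
  int <- 0.5 - 3 / (m + 2) + 3 / (2 * m + 2) - 1 / (3 * m + 2)
  2 * c3 * int
}

# Axial stations (z, R) per section; blunted sections are resolved separately
# so no station interval straddles the shoulder step.
reduced_stations <- function(geom, opts) {
  ns <- opts$n_stations
  if (geom$shape == "blunted") {
    z_up <- seq(0, geom$l_upper, length.out = ns + 1)
    z_lo <- seq(geom$l_upper, nozzle_length(geom), length.out = ns + 1)
    list(upper = list(z = z_up, r = rep(geom$r_big, ns + 1)),
         lower = list(z = z_lo, r = rep(geom$r_small, ns + 1)))
  } else {
    z_up <- seq(0, geom$l_upper, length.out = ns + 1)
    z_lo <- seq(geom$l_upper, nozzle_length(geom), length.out = ns + 1)
    list(upper = list(z = z_up, r = radius_profile(geom, z_up)),
         lower = list(z = z_lo, r = radius_profile(geom, z_lo)))
  }
}

#' Pressure required to push a flow rate through a nozzle (quasi-1D)
#'
#' Segment-wise lubrication model: at every axial station the local fully
#' developed power-law wall shear \eqn{\tau_w(z) = K[(3n+1)Q/(n\pi R(z)^3)]^n}
#' gives the local pressure gradient \eqn{2\tau_w/R}, integrated over the
#' nozzle; an inertial (kinetic-energy) term
#' \eqn{\alpha \tfrac{1}{2}\rho (V_{exit}^2 - V_{inlet}^2)} accounts for the
#' acceleration into the narrow exit. Strictly increasing in `q`.
#'
#' @param q flow rate in m^3/s (> 0).
#' @param geom a `nozzle_geometry`.
#' @param mat a [material()].
#' @param opts a [reduced_options()].
#' @return required pressure difference in Pa, vectorized over `q`.
#' @export
pressure_required <- function(q, geom, mat, opts = reduced_options()) {
  validate_geometry(geom)
  st <- reduced_stations(geom, opts)
  alpha <- if (opts$alpha_mode == "plug") 1 else alpha_energy(mat$n)
  vapply(q, function(qi) {
    if (qi <= 0) stop("q must be positive", call. = FALSE)
    visc <- 0
    segs <- if (opts$include_upper) st else st["lower"]
    for (s in segs) {
      grad <- 2 * pipe_wall_shear_at_flow(qi, s$r, mat) / s$r
      visc <- visc + sum(diff(s$z) * (grad[-1] + grad[-length(grad)]) / 2)
    }
    v_in <- qi / (pi * geom$r_big^2)
    v_out <- qi / (pi * geom$r_small^2)
    visc + alpha * 0.5 * mat$rho * (v_out^2 - v_in^2)
  }, numeric(1))
}

#' Solve nozzle flow with the quasi-1D reduced model
#'
#' Flow-driven mode evaluates the model directly; pressure-driven mode
#' root-finds the unique flow rate with `pressure_required(q) == delta_p`
#' (bracketed bisection on log q, relative tolerance 1e-8). The maximum shear
#' stress is the largest fully developed wall value over all stations — it
#' deliberately excludes the corner/exit stress concentrations that only a
#' multidimensional solver resolves, and is therefore a lower bound on the
#' finite-volume MSS.
#'
#' @param geom a `nozzle_geometry`.
#' @param mat a [material()].
#' @param drive a [pressure_drive()] or [flow_drive()].
#' @param opts a [reduced_options()].
#' @return a one-row `flow_summary` tibble (see [new_flow_summary] fields) with
#'   the wall shear/pressure profile in the `wall` list-column.
#' @export
#' @examples
#' solve_reduced(blunted_nozzle(0.25, 3.5, 6, 4),
#'               builtin_material("Alginate"), pressure_drive(340))
solve_reduced <- function(geom, mat, drive, opts = reduced_options()) {
  validate_geometry(geom)
  stopifnot(inherits(drive, "drive_condition"))
  if (drive$mode == "flowrate") {
    q <- drive$q_in
    delta_p <- pressure_required(q, geom, mat, opts)
  } else {
    delta_p <- drive$delta_p
    q <- .invert_pressure(delta_p, geom, mat, opts)
  }
  st <- reduced_stations(geom, opts)
  z <- c(st$upper$z, st$lower$z)
  r <- c(st$upper$r, st$lower$r)
  tau <- pipe_wall_shear_at_flow(q, r, mat)
  # mechanical-energy static pressure along the axis (viscous + acceleration)
  alpha <- if (opts$alpha_mode == "plug") 1 else alpha_energy(mat$n)
  grad <- 2 * tau / r
  dvisc <- c(0, cumsum(diff(z) * (grad[-1] + grad[-length(grad)]) / 2))
  v <- q / (pi * r^2)
  p <- delta_p - dvisc - alpha * 0.5 * mat$rho * (v^2 - v[1]^2)
  imax <- which.max(tau)
  nu_exit <- .exit_kinematic_viscosity(q, geom$r_small, mat, opts$gamma_dot_min)
  wall <- tibble::tibble(z_mm = m_to_mm(z), r_mm = m_to_mm(r),
                         tau_w_kpa = pa_to_kpa(tau), p_kpa = pa_to_kpa(p))
  new_flow_summary(mss = max(tau), q = q, delta_p = delta_p, nu_exit = nu_exit,
                   r_small = geom$r_small, solver = "reduced",
                   mss_z = z[imax], mss_r = r[imax], wall = wall)
}

# Bracketed bisection on log q; bracket expanded until it straddles delta_p.
.invert_pressure <- function(delta_p, geom, mat, opts, max_iter = 200) {
  f <- function(lq) pressure_required(exp(lq), geom, mat, opts) - delta_p
  # analytic straight-tube inverse through the exit radius as starting point
  tube <- pipe_spec(geom$r_small, nozzle_length(geom))
  q0 <- pipe_flow_rate(tube, pipe_mean_velocity(delta_p, tube, mat))
  lo <- log(q0); hi <- log(q0)
  it <- 0
  while (f(lo) > 0) { lo <- lo - 1; it <- it + 1
    if (it > max_iter) stop("pressure inversion: bracket expansion failed (low side); ",
                            "f(", exp(lo), ") still above target", call. = FALSE) }
  while (f(hi) < 0) { hi <- hi + 1; it <- it + 1
    if (it > max_iter) stop("pressure inversion: bracket expansion failed (high side); ",
                            "f(", exp(hi), ") still below target", call. = FALSE) }
  ur <- stats::uniroot(f, c(lo, hi), tol = 1e-10, maxiter = max_iter)
  exp(ur$root)
}

# Area-averaged kinematic viscosity over the fully developed exit profile,
# with the shear-rate floor keeping the axis value finite.
.exit_kinematic_viscosity <- function(q, r_small, mat, gamma_dot_min) {
  gw <- (3 * mat$n + 1) * q / (mat$n * pi * r_small^3)
  f <- function(x) pl_viscosity(mat, gw * x^(1 / mat$n), gamma_dot_min) * x
  2 * stats::integrate(f, 0, 1, rel.tol = 1e-8)$value / mat$rho
}
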