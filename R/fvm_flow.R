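#' Numerics options for the finite-volume solver
#'
#' @param relax_u,relax_p under-relaxation factors for velocity and pressure
#'   (in (0,1)), or `NULL` (default) to pick them by flow regime:
#'   (0.5, 0.2) for straight-through geometries, (0.3, 0.1) when the
#'   barrel-to-exit contraction exceeds a factor 2 (where the regularized
#'   viscosity contrast spans several decades), scaled down further at high
#'   generalized Reynolds number. Explicit values are used as given.
#' @param relax_eta under-relaxation of the viscosity update.
#' @param tol residual target on the normalized mass and momentum residuals.
#' @param max_outer outer-iteration cap.
#' @param gamma_dot_min shear-rate regularization floor (1/s); the power-law
#'   viscosity diverges at vanishing shear rate for n < 1 and is held at
#'   K*gamma_dot_min^(n-1) below the floor.
#' @param n_psweeps pressure-correction ADI sweeps per outer iteration.
#' @param verbose_every print residuals every this many iterations (0 = quiet).
#' @return a `numerics_options` list.
#' @export
numerics_options <- function(relax_u = NULL, relax_p = NULL, relax_eta = 0.4,
                             tol = 1e-6, max_outer = 20000,
                             gamma_dot_min = 1e-3, n_psweeps = 4,
                             verbose_every = 0) {
  stopifnot(is.null(relax_u) || (relax_u > 0 && relax_u < 1),
            is.null(relax_p) || (relax_p > 0 && relax_p < 1))
  list(relax_u = relax_u, relax_p = relax_p, relax_eta = relax_eta,
       tol = tol, max_outer = as.integer(max_outer),
       gamma_dot_min = gamma_dot_min, n_psweeps = as.integer(n_psweeps),
       verbose_every = as.integer(verbose_every))
}

#' Build a structured axisymmetric mesh for a nozzle
#'
#' Staggered-grid mesh of the wetted domain with a stepwise (staircase) wall
#' mask following [radius_profile()]. The radial spacing is uniform (`dr`)
#' from the axis out to `r_fine` — which always covers the exit radius, where
#' the wall shear peaks — and then grows geometrically to the barrel radius.
#' The axial spacing is uniform (`dz`) over the lower section and coarsens
#' geometrically up the barrel. `dr = 0.005` mm and `dz = 0.010` mm reproduce
#' the reference grid of the lower nozzle.
#'
#' @param geom a `nozzle_geometry`.
#' @param dr fine radial spacing (m); must satisfy `dr <= r_small/4`.
#' @param dz fine axial spacing (m) for the lower section.
#' @param r_fine radius (m) out to which `dr` stays uniform; default
#'   `1.6 * r_small` (capped at the barrel radius).
#' @param growth geometric growth ratio of the coarsened spacings.
#' @param dz_upper_max cap on the axial spacing in the upper section (m).
#' @param dz_lower_growth optional geometric growth of the axial spacing in
#'   the lower section away from the exit (1 = uniform, the reference grid).
#' @return a `nozzle_mesh` list with face coordinates `rf`, `zf`, fluid-cell
#'   counts `nfluid` per column, and cell-centre vectors.
#' @export
build_mesh <- function(geom, dr = 0.005e-3, dz = 0.010e-3, r_fine = NULL,
                       growth = 1.2, dz_upper_max = NULL,
                       dz_lower_growth = 1) {
  validate_geometry(geom)
  if (dr > geom$r_small / 4 + 1e-15)
    stop("radial spacing too coarse: need dr <= r_small/4 (", geom$r_small / 4,
         " m)", call. = FALSE)
  if (is.null(r_fine)) r_fine <- min(1.6 * geom$r_small, geom$r_big)
  r_fine <- min(max(r_fine, geom$r_small), geom$r_big)
  # radial faces: uniform to r_fine (face exactly at r_small), then geometric
  n_fine <- max(round(r_fine / dr), 4)
  # snap so that a face lies exactly on r_small
  n_rs <- max(round(geom$r_small / dr), 4)
  dr_eff <- geom$r_small / n_rs
  n_fine <- max(n_rs, round(r_fine / dr_eff))
  rf <- seq(0, n_fine * dr_eff, by = dr_eff)
  while (utils::tail(rf, 1) < geom$r_big - 1e-12) {
    step <- min((utils::tail(rf, 1) - utils::tail(rf, 2)[1]) * growth,
                geom$r_big - utils::tail(rf, 1))
    rf <- c(rf, utils::tail(rf, 1) + step)
  }
  rf[length(rf)] <- geom$r_big
  # merge a final sliver cell
  nr <- length(rf)
  if (nr >= 3 && (rf[nr] - rf[nr - 1]) < 0.3 * (rf[nr - 1] - rf[nr - 2]))
    rf <- rf[-(nr - 1)]

  # axial faces: upper section coarsened, lower section uniform dz (or gently
  # graded away from the exit when dz_lower_growth > 1)
  L <- nozzle_length(geom)
  if (is.null(dz_upper_max)) dz_upper_max <- geom$l_upper / 8
  zf_up <- .graded_faces(geom$l_upper, dz_first = dz_upper_max,
                         dz_last = max(dz, geom$l_upper / 400),
                         growth = growth)
  if (dz_lower_growth <= 1) {
    n_lo <- max(round(geom$l_lower / dz), 8)
    zf_lo <- seq(0, geom$l_lower, length.out = n_lo + 1)
  } else {
    zf_lo <- rev(geom$l_lower - .graded_faces(geom$l_lower, dz_first = 40 * dz,
                                              dz_last = dz,
                                              growth = dz_lower_growth))
  }
  zf <- c(zf_up, geom$l_upper + zf_lo[-1])
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  rwall <- radius_profile(geom, zc)
  nfluid <- vapply(rwall, function(R) sum(rc < R), integer(1))
  if (any(nfluid < 4)) stop("mesh error: fewer than 4 cells across a section",
                            call. = FALSE)
  structure(list(rf = rf, zf = zf, rc = rc, zc = zc,
                 dr = diff(rf), dz = diff(zf),
                 nfluid = as.integer(nfluid), geom = geom),
            class = "nozzle_mesh")
}

# geometric face ladder over [0, L] starting coarse and ending fine
.graded_faces <- function(L, dz_first, dz_last, growth) {
  dz_last <- min(dz_last, L / 4)
  dz_first <- max(dz_first, dz_last)
  steps <- dz_last
  while (sum(steps) < L - 1e-15) {
    nxt <- min(utils::tail(steps, 1) * growth, dz_first, L - sum(steps))
    steps <- c(steps, nxt)
  }
  zf <- cumsum(c(0, rev(steps)))
  zf[length(zf)] <- L
  zf
}

#' @export
print.nozzle_mesh <- function(x, ...) {
  cat(sprintf("<nozzle_mesh> %d x %d cells (%d fluid), dr_min = %.3g mm, dz_min = %.3g mm\n",
              length(x$rc), length(x$zc), sum(x$nfluid),
              m_to_mm(min(x$dr)), m_to_mm(min(x$dz))))
  invisible(x)
}

#' Solve nozzle flow with the axisymmetric finite-volume model
#'
#' Steady laminar SIMPLE-type pressure-velocity coupling on a staggered grid,
#' first-order upwind convection, viscosity updated every outer iteration
#' from the power-law (with shear-rate floor) evaluated on the full
#' strain-rate second invariant. No-slip walls, uniform plug inflow, fixed
#' outlet pressure. In flow-rate mode the inlet velocity is prescribed
#' directly; in pressure mode the unique flow rate whose computed
#' inlet-outlet (area-averaged static) pressure difference equals the target
#' is found by a secant iteration in log-log space, started from the quasi-1D
#' solution, so the converged state satisfies the constant-pressure boundary
#' condition.
#'
#' @param geom a `nozzle_geometry`.
#' @param mat a [material()].
#' @param drive a [pressure_drive()] or [flow_drive()].
#' @param mesh optional [build_mesh()] result (default: reference-resolution
#'   lower nozzle with coarsened barrel).
#' @param numerics a [numerics_options()].
#' @param pressure_rtol relative tolerance on the matched pressure in
#'   pressure mode.
#' @param keep_fields keep the full 2D fields in the `field` attribute-column.
#' @return a one-row `flow_summary` tibble; the `field` list-column holds the
#'   [fvm_field] (velocities, pressure, viscosity, strain rate, stress,
#'   residual history) when `keep_fields = TRUE`.
#' @export
solve_fvm <- function(geom, mat, drive, mesh = NULL,
                      numerics = numerics_options(), pressure_rtol = 5e-3,
                      keep_fields = TRUE) {
  validate_geometry(geom)
  if (is.null(mesh)) mesh <- build_mesh(geom)
  stopifnot(inherits(mesh, "nozzle_mesh"))
  if (drive$mode == "flowrate") {
    field <- .fvm_run(mesh, mat, drive$q_in, numerics)
    return(.fvm_summarize(field, mesh, mat, keep_fields))
  }
  target <- drive$delta_p
  # secant on log(dp) vs log(q), warm-started from the quasi-1D inverse
  q0 <- solve_reduced(geom, mat, drive)$q_m3_s
  f0 <- .fvm_run(mesh, mat, q0, numerics)
  dp0 <- f0$delta_p
  if (abs(dp0 / target - 1) < pressure_rtol)
    return(.fvm_summarize(f0, mesh, mat, keep_fields))
  # local slope from the reduced model: dp ~ q^s
  s <- local({
    p1 <- pressure_required(q0, geom, mat)
    p2 <- pressure_required(q0 * 1.05, geom, mat)
    log(p2 / p1) / log(1.05)
  })
  q1 <- q0 * (target / dp0)^(1 / s)
  best <- f0
  fprev <- f0; qprev <- q0
  for (it in seq_len(12)) {
    f1 <- .fvm_run(mesh, mat, q1, numerics, init = fprev, q_init = qprev,
                   dp_ratio = (q1 / qprev)^s)
    fprev <- f1; qprev <- q1
    dp1 <- f1$delta_p
    if (abs(dp1 - target) < abs(best$delta_p - target)) best <- f1
    if (abs(dp1 / target - 1) < pressure_rtol)
      return(.fvm_summarize(f1, mesh, mat, keep_fields))
    slope <- log(dp1 / dp0) / log(q1 / q0)
    if (!is.finite(slope) || slope <= 0) slope <- s
    q0 <- q1; dp0 <- dp1
    q1 <- q1 * (target / dp1)^(1 / slope)
  }
  warning("pressure matching stopped at |dp/target - 1| = ",
          signif(abs(best$delta_p / target - 1), 3), call. = FALSE)
  .fvm_summarize(best, mesh, mat, keep_fields)
}

# one flow-driven FVM solve; returns the raw field list. When no explicit
# relaxation is given it is picked by regime: straight-through geometries
# iterate stably at (0.5, 0.2); strong contractions (barrel/exit radius
# ratio > 2, several decades of regularized-viscosity contrast) need
# (0.3, 0.1), scaled down further with the generalized (Metzner-Reed)
# Reynolds number of the exit tube; divergence halves the factors again
# (twice at most).
.fvm_run <- function(mesh, mat, q, num, init = NULL, q_init = NA,
                     dp_ratio = 1) {
  a_in <- sum(mesh$rc[seq_len(mesh$nfluid[1])] * mesh$dr[seq_len(mesh$nfluid[1])])
  v_in <- (q / (2 * pi)) / a_in
  re <- generalized_reynolds(q, mesh$geom$r_small, mat)
  if (re > 2000)
    warning("generalized Reynolds number ", round(re),
            " above 2000: laminar model questionable", call. = FALSE)
  if (is.null(num$relax_u) || is.null(num$relax_p)) {
    contraction <- mesh$geom$r_big / mesh$geom$r_small
    base <- if (contraction < 2) c(0.5, 0.2) else c(0.3, 0.1)
    fac <- if (re < 50) 1 else if (re < 300) 0.5 else 0.25
    num$relax_u <- num$relax_u %||% (base[1] * fac)
    num$relax_p <- num$relax_p %||% (base[2] * fac)
  }
  out <- NULL
  for (attempt in 1:3) {
    out <- .fvm_solve_cpp(mesh$rf, mesh$zf, mesh$nfluid,
                          mat$rho, mat$k, mat$n, num$gamma_dot_min, v_in,
                          num$relax_u, num$relax_p, num$relax_eta,
                          num$tol, num$max_outer, num$n_psweeps,
                          num$verbose_every,
                          if (is.null(init)) NULL else
                            init[c("u", "v", "p")],
                          if (is.na(q_init)) 1 else q / q_init,
                          dp_ratio)
    if (is.null(out$error)) break
    if (attempt == 3)
      stop("FVM solver diverged: ", out$error, call. = FALSE)
    num$relax_u <- num$relax_u / 2
    num$relax_p <- num$relax_p / 2
    num$max_outer <- as.integer(num$max_outer * 2)
    warning("FVM divergence; retrying with relax_u = ", num$relax_u,
            ", relax_p = ", num$relax_p, call. = FALSE)
  }
  if (!isTRUE(out$converged)) {
    rm <- utils::tail(out$resid_mass, 1)
    ru <- utils::tail(out$resid_u, 1)
    if (rm > 100 * num$tol || ru > 100 * num$tol)
      stop(sprintf(paste0("FVM solver did not converge in %d iterations ",
                          "(mass %.2e, momentum %.2e vs tol %.0e); residual ",
                          "history attached"),
                   out$iterations, rm, ru, num$tol), call. = FALSE)
    warning(sprintf("FVM residual stagnation near tolerance (mass %.2e, momentum %.2e)",
                    rm, ru), call. = FALSE)
  }
  out$q <- out$q_per_2pi * 2 * pi
  out$delta_p <- out$p_in_avg  # outlet plane is the zero reference
  out$mesh <- mesh
  out$gamma_dot_min <- num$gamma_dot_min
  class(out) <- "fvm_field"
  out
}

#' @export
print.fvm_field <- function(x, ...) {
  cat(sprintf("<fvm_field> %s after %d iterations; Q = %.4g µL/s, dp = %.4g kPa\n",
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations, m3s_to_uls(x$q), pa_to_kpa(x$delta_p)))
  invisible(x)
}

# FlowSummary from a converged field: MSS (location), outlet flux, outlet
# area-averaged kinematic viscosity, wall shear profile
.fvm_summarize <- function(field, mesh, mat, keep_fields = TRUE) {
  tau <- field$eta * field$gamma_dot
  imax <- which.max(tau)  # NA cells excluded by which.max
  ij <- arrayInd(imax, dim(tau))
  nz <- length(mesh$zc)
  nf <- mesh$nfluid
  # outlet-plane averages
  iout <- seq_len(nf[nz])
  w <- mesh$rc[iout] * mesh$dr[iout]
  nu_exit <- sum(field$eta[iout, nz] * w) / sum(w) / mat$rho
  # wall shear: stress in the wall-adjacent cell of each column
  iw <- pmax(nf, 1)
  tau_w <- vapply(seq_len(nz), function(j) tau[iw[j], j], numeric(1))
  p_w <- vapply(seq_len(nz), function(j) field$p[iw[j], j], numeric(1))
  wall <- tibble::tibble(z_mm = m_to_mm(mesh$zc),
                         r_mm = m_to_mm(mesh$rf[nf + 1]),
                         tau_w_kpa = pa_to_kpa(tau_w),
                         p_kpa = pa_to_kpa(p_w))
  extra <- list(iterations = field$iterations,
                converged = isTRUE(field$converged),
                resid_mass = utils::tail(field$resid_mass, 1),
                field = if (keep_fields) list(field) else list(NULL))
  new_flow_summary(mss = max(tau, na.rm = TRUE), q = field$q,
                   delta_p = field$delta_p, nu_exit = nu_exit,
                   r_small = mesh$geom$r_small, solver = "fvm",
                   mss_z = mesh$zc[ij[2]], mss_r = mesh$rc[ij[1]],
                   wall = wall, extra = extra)
}

#' Cross-section flux profile of a finite-volume solution
#'
#' Axial volumetric flux through every cross-section; after convergence all
#' values match the outlet flow rate to well under a percent (discrete mass
#' conservation).
#'
#' @param field an `fvm_field` (from the `field` column of a [solve_fvm()]
#'   summary).
#' @return tibble with `z_mm` (face positions) and `q_ul_s`.
#' @export
section_fluxes <- function(field) {
  mesh <- field$mesh
  nzf <- length(mesh$zf)
  q <- vapply(seq_len(nzf), function(jf) {
    j <- min(max(jf - 1, 1), length(mesh$zc))
    nfj <- if (jf == 1) mesh$nfluid[1]
           else if (jf == nzf) mesh$nfluid[length(mesh$zc)]
           else min(mesh$nfluid[jf - 1], mesh$nfluid[jf])
    i <- seq_len(nfj)
    2 * pi * sum(mesh$rc[i] * mesh$dr[i] * field$u[i, jf])
  }, numeric(1))
  tibble::tibble(z_mm = m_to_mm(mesh$zf), q_ul_s = m3s_to_uls(q))
}

#' Grid-refinement (convergence) study
#'
#' Re-solves one configuration on successively finer meshes and reports the
#' flow rate and maximum shear stress per level together with the
#' Richardson-extrapolated flow rate from the two finest levels.
#'
#' @param geom,mat,drive as in [solve_fvm()].
#' @param levels list of `c(dr, dz)` pairs in metres, coarse to fine (>= 3).
#' @param numerics a [numerics_options()].
#' @return a tibble with one row per level (`dr_mm`, `dz_mm`, `mss_kpa`,
#'   `flow_ul_s`, `delta_p_kpa`, `converged`) carrying the extrapolated flow
#'   rate in attribute `q_richardson_ul_s`.
#' @export
grid_refinement_study <- function(geom, mat, drive, levels,
                                  numerics = numerics_options()) {
  if (length(levels) < 3) stop("need at least 3 refinement levels", call. = FALSE)
  rows <- purrr::map(levels, function(lv) {
    out <- tryCatch({
      mesh <- build_mesh(geom, dr = lv[1], dz = lv[2])
      fs <- solve_fvm(geom, mat, drive, mesh = mesh, numerics = numerics,
                      keep_fields = FALSE)
      tibble::tibble(dr_mm = m_to_mm(lv[1]), dz_mm = m_to_mm(lv[2]),
                     mss_kpa = fs$mss_kpa, flow_ul_s = fs$flow_ul_s,
                     delta_p_kpa = fs$delta_p_kpa, converged = fs$converged)
    }, error = function(e)
      tibble::tibble(dr_mm = m_to_mm(lv[1]), dz_mm = m_to_mm(lv[2]),
                     mss_kpa = NA_real_, flow_ul_s = NA_real_,
                     delta_p_kpa = NA_real_, converged = FALSE))
    out
  })
  out <- dplyr::bind_rows(rows)
  fin <- which(out$converged)
  if (length(fin) >= 3) {
    q <- out$flow_ul_s[utils::tail(fin, 3)]
    denom <- q[2] - q[1]
    attr(out, "q_richardson_ul_s") <-
      if (abs(denom) > 0 && abs((q[3] - q[2]) / denom) < 1)
        q[3] + (q[3] - q[2])^2 / (denom - (q[3] - q[2]))
      else q[3]
  }
  out
}

#' Export a finite-volume field to legacy VTK (rectilinear grid)
#'
#' Writes cell-centred velocity, pressure, viscosity, strain rate and stress
#' for inspection in ParaView or similar.
#'
#' @param field an `fvm_field`.
#' @param path output file path (`.vtk`).
#' @return the path, invisibly.
#' @export
write_vtk <- function(field, path) {
  mesh <- field$mesh
  nr <- length(mesh$rc); nz <- length(mesh$zc)
  uc <- (field$u[, -1, drop = FALSE] + field$u[, -(nz + 1), drop = FALSE]) / 2
  vc <- (field$v[-1, , drop = FALSE] + field$v[-(nr + 1), , drop = FALSE]) / 2
  num <- function(x) formatC(x, format = "g", digits = 9)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric nozzle flow (r = y, z = x)", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", nz + 1, nr + 1),
               sprintf("X_COORDINATES %d double", nz + 1),
               paste(num(mesh$zf), collapse = " "),
               sprintf("Y_COORDINATES %d double", nr + 1),
               paste(num(mesh$rf), collapse = " "),
               "Z_COORDINATES 1 double", "0"), con)
  writeLines(sprintf("CELL_DATA %d", nr * nz), con)
  wr <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"),
               con)
    vals <- as.vector(t(m))  # x (=z) fastest
    vals[!is.finite(vals)] <- 0
    writeLines(paste(num(vals), collapse = " "), con)
  }
  wr("u_axial", uc); wr("u_radial", vc); wr("pressure", field$p)
  wr("viscosity", field$eta); wr("gamma_dot", field$gamma_dot)
  wr("tau", field$eta * field$gamma_dot)
  fluid <- matrix(0, nr, nz)
  for (j in seq_len(nz)) fluid[seq_len(mesh$nfluid[j]), j] <- 1
  wr("fluid", fluid)
  invisible(path)
}

#' Generalized (Metzner-Reed) Reynolds number of a power-law tube flow
#'
#' \deqn{Re = \frac{\rho V^{2-n} D^n}{8^{n-1} K ((3n+1)/(4n))^n}}
#' with V the mean velocity and D the tube diameter.
#'
#' @param q flow rate (m^3/s).
#' @param r tube radius (m).
#' @param mat a [material()].
#' @return dimensionless Reynolds number.
#' @export
generalized_reynolds <- function(q, r, mat) {
  v <- q / (pi * r^2)
  d <- 2 * r
  mat$rho * v^(2 - mat$n) * d^mat$n /
    (8^(mat$n - 1) * mat$k * ((3 * mat$n + 1) / (4 * mat$n))^mat$n)
}
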