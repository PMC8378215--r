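#' Printing drive condition
#'
#' Extrusion is driven either by a constant net pressure difference between
#' inlet and outlet (pressure-driven printing) or by a constant volumetric
#' flow rate (flow-driven printing). Exactly one of the two is set.
#'
#' @param delta_p_kpa net inlet-outlet pressure difference in kPa (> 0).
#' @param q_uls volumetric flow rate in µL/s (> 0).
#' @return an object of class `drive_condition` with SI fields.
#' @export
#' @examples
#' pressure_drive(340)
#' flow_drive(3500)
pressure_drive <- function(delta_p_kpa) {
  if (!is.numeric(delta_p_kpa) || length(delta_p_kpa) != 1 ||
      !is.finite(delta_p_kpa) || delta_p_kpa <= 0)
    stop("pressure drive requires a single positive pressure in kPa", call. = FALSE)
  structure(list(mode = "pressure", delta_p = kpa_to_pa(delta_p_kpa),
                 q_in = NA_real_), class = "drive_condition")
}

#' @rdname pressure_drive
#' @export
flow_drive <- function(q_uls) {
  if (!is.numeric(q_uls) || length(q_uls) != 1 || !is.finite(q_uls) || q_uls <= 0)
    stop("flow drive requires a single positive flow rate in µL/s", call. = FALSE)
  structure(list(mode = "flowrate", delta_p = NA_real_,
                 q_in = uls_to_m3s(q_uls)), class = "drive_condition")
}

#' @export
print.drive_condition <- function(x, ...) {
  if (x$mode == "pressure") {
    cat(sprintf("<drive_condition> constant pressure, delta_p = %g kPa\n",
                pa_to_kpa(x$delta_p)))
  } else {
    cat(sprintf("<drive_condition> constant flow rate, Q = %g µL/s\n",
                m3s_to_uls(x$q_in)))
  }
  invisible(x)
}

# Assemble the standard one-row flow summary tibble shared by all solvers.
# SI inputs; reported columns follow the printing conventions (kPa, µL/s, m/s,
# m^2/s) with SI duplicates for programmatic use.
new_flow_summary <- function(mss, q, delta_p, nu_exit, r_small, solver,
                             mss_z = NA_real_, mss_r = NA_real_,
                             wall = NULL, extra = list()) {
  v_exit <- q / (pi * r_small^2)
  out <- tibble::tibble(
    solver = solver,
    mss_kpa = pa_to_kpa(mss),
    flow_ul_s = m3s_to_uls(q),
    v_exit_m_s = v_exit,
    nu_exit_m2_s = nu_exit,
    delta_p_kpa = pa_to_kpa(delta_p),
    mss_pa = mss,
    q_m3_s = q,
    delta_p_pa = delta_p,
    mss_z_mm = m_to_mm(mss_z),
    mss_r_mm = m_to_mm(mss_r),
    wall = list(wall)
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("flow_summary", class(out))
  out
}

#' Wall shear profile of a flow summary
#'
#' @param fs a one-row flow summary as returned by [solve_nozzle()].
#' @return a tibble with columns `z_mm`, `r_mm`, `tau_w_kpa`, `p_kpa`.
#' @export
wall_profile <- function(fs) {
  stopifnot(inherits(fs, "flow_summary"), nrow(fs) == 1)
  fs$wall[[1]]
}
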