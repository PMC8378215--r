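#' Solve nozzle flow with the selected solver
#'
#' Unified front end over the quasi-1D reduced model ([solve_reduced()]) and
#' the 2D axisymmetric finite-volume solver ([solve_fvm()]).
#'
#' @param geom a `nozzle_geometry`.
#' @param mat a [material()].
#' @param drive a [pressure_drive()] or [flow_drive()].
#' @param solver `"reduced"` or `"fvm"`.
#' @param ... solver-specific options: `opts = reduced_options()` for the
#'   reduced model; `mesh`/`numerics = numerics_options()` for the FVM.
#' @return a one-row `flow_summary` tibble.
#' @export
solve_nozzle <- function(geom, mat, drive, solver = c("reduced", "fvm"), ...) {
  solver <- match.arg(solver)
  if (solver == "reduced") solve_reduced(geom, mat, drive, ...)
  else solve_fvm(geom, mat, drive, ...)
}
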