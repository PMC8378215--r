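#' Read and validate a run configuration
#'
#' A YAML (or JSON) configuration describes one analysis run in the table
#' units of the printing literature (mm, kPa, µL/s). Unknown keys are
#' rejected; all defaults are made explicit in the returned "resolved"
#' configuration, which also carries the seed and package version as a
#' provenance block.
#'
#' Top-level keys: `task` (one of `"simulate"`, `"campaign"`, `"sweep"`,
#' `"viability"`), `material` (either `name:` of a built-in ink or
#' `rho`/`k`/`n`), `geometry` (`shape`, `r_small_mm`, `r_big_mm`,
#' `l_lower_mm`, `l_upper_mm`, and `r_middle_mm` for conical), `drive`
#' (`pressure_kpa` or `flow_ul_s`), `solver` (`"reduced"` or `"fvm"`),
#' `campaign` (`n`, `seed`, `shape`), `output_dir`.
#'
#' @param path YAML/JSON file path.
#' @return a resolved configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  resolve_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @export
resolve_run_config <- function(cfg) {
  allowed <- c("task", "material", "geometry", "drive", "solver", "campaign",
               "output_dir", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  task <- match.arg(cfg$task %||% "simulate",
                    c("simulate", "campaign", "sweep", "viability"))
  mat_block <- cfg$material %||% list(name = "Alginate")
  mat <- if (!is.null(mat_block$name)) builtin_material(mat_block$name)
         else material(mat_block$label %||% "custom", rho = mat_block$rho,
                       k = mat_block$k, n = mat_block$n,
                       pressure_kpa = mat_block$pressure_kpa %||% NA_real_)
  geo_block <- cfg$geometry %||%
    list(shape = "blunted", r_small_mm = 0.25, r_big_mm = 3.5,
         l_lower_mm = 6, l_upper_mm = 4)
  geom <- geometry_from_row(geo_block$shape %||% "blunted",
                            list(r_small_mm = geo_block$r_small_mm,
                                 r_middle_mm = geo_block$r_middle_mm %||% NA_real_,
                                 r_big_mm = geo_block$r_big_mm,
                                 l_lower_mm = geo_block$l_lower_mm,
                                 l_upper_mm = geo_block$l_upper_mm))
  drive_block <- cfg$drive %||% list(pressure_kpa = mat$pressure_kpa)
  if (!is.null(drive_block$pressure_kpa) && !is.null(drive_block$flow_ul_s))
    stop("drive block must set exactly one of pressure_kpa / flow_ul_s",
         call. = FALSE)
  drive <- if (!is.null(drive_block$flow_ul_s)) flow_drive(drive_block$flow_ul_s)
           else pressure_drive(drive_block$pressure_kpa)
  structure(list(
    task = task, material = mat, geometry = geom, drive = drive,
    solver = match.arg(cfg$solver %||% "reduced", c("reduced", "fvm")),
    campaign = list(n = cfg$campaign$n %||% 200L,
                    seed = cfg$campaign$seed %||% cfg$seed %||% 1L,
                    shape = cfg$campaign$shape %||% geom$shape),
    seed = cfg$seed %||% 1L,
    output_dir = cfg$output_dir %||% NULL,
    provenance = list(package_version = as.character(utils::packageVersion("nozzleflow")))
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a resolved run configuration
#'
#' Dispatches on the configured task: `simulate` returns a one-row flow
#' summary; `campaign` generates the Latin-hypercube design and runs it;
#' `sweep` runs the shear-thinning sweep; `viability` recomputes the
#' literature study points. Results are returned as tibbles and, when
#' `output_dir` is set, also written as deterministic CSV via
#' [write_summary()].
#'
#' @param config a [read_run_config()] result.
#' @return task-dependent tibble.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- switch(config$task,
    simulate = solve_nozzle(config$geometry, config$material, config$drive,
                            solver = config$solver),
    campaign = {
      des <- lhs_design(config$campaign$shape, n = config$campaign$n,
                        seed = config$campaign$seed)
      run_campaign(des, config$material, config$drive, solver = config$solver)
    },
    sweep = shear_thinning_sweep(shape = config$geometry$shape,
                                 drive = config$drive, solver = config$solver),
    viability = simulate_records(builtin_studies(), solver = config$solver)
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    drop_cols <- intersect(c("wall", "field", "boot"), names(out))
    write_summary(out[setdiff(names(out), drop_cols)],
                  file.path(config$output_dir, paste0(config$task, ".csv")))
  }
  out
}

#' Write a deterministic CSV summary
#'
#' Fixed column order as passed, numbers formatted to 9 significant digits
#' (round-trip lossless at that precision, stable across runs for
#' deterministic solvers).
#'
#' @param rows a data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary <- function(rows, path) {
  rows <- as.data.frame(rows)
  fmt <- function(x) {
    if (is.double(x)) {
      out <- formatC(x, format = "g", digits = 9)
      out[is.na(x)] <- ""
      out
    } else x
  }
  out <- as.data.frame(lapply(rows, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the analytic-oracle verification suite
#'
#' Quick end-to-end checks of the solver chain against the closed-form
#' power-law Poiseuille solution: the quasi-1D model on a straight tube, the
#' pressure/flow round trip, and (optionally) the finite-volume solver on a
#' short tube. Returns one row per check with the measured relative error.
#'
#' @param include_fvm include the (slower) finite-volume check.
#' @return tibble with `check`, `error`, `tolerance`, `pass`.
#' @export
verify_oracles <- function(include_fvm = FALSE) {
  alg <- builtin_material("Alginate")
  rows <- list()
  # quasi-1D on a straight tube vs closed form (viscous part)
  tube <- pipe_spec(0.25e-3, 10e-3)
  q <- uls_to_m3s(20)
  dp_an <- pipe_pressure_for_flow(q, tube, alg)
  geom <- blunted_nozzle(0.25, 0.2505, 10 - 1e-4, 1e-4)
  dp_red <- pressure_required(q, geom, alg,
                              reduced_options(alpha_mode = "plug"))
  ke <- 0.5 * alg$rho * (q / (pi * 0.25e-3^2))^2
  rows$reduced_tube <- abs((dp_red - ke) / dp_an - 1)
  # round trip
  fs <- solve_reduced(geom, alg, pressure_drive(200))
  rows$round_trip <- abs(pressure_required(fs$q_m3_s, geom, alg) / 2e5 - 1)
  # kinetic-energy factor vs quadrature
  a_quad <- local({
    n <- alg$n; m <- (n + 1) / n; cc <- (3 * n + 1) / (n + 1)
    2 * cc^3 * stats::integrate(function(x) (1 - x^m)^3 * x, 0, 1)$value
  })
  rows$alpha_quadrature <- abs(alpha_energy(alg$n) / a_quad - 1)
  tol <- c(reduced_tube = 0.01, round_trip = 1e-6, alpha_quadrature = 1e-8)
  if (include_fvm) {
    g2 <- blunted_nozzle(0.25, 0.26, 5, 0.2)
    fs2 <- suppressWarnings(
      solve_fvm(g2, alg, flow_drive(50),
                mesh = build_mesh(g2, dr = 0.005e-3, dz = 0.05e-3),
                numerics = numerics_options(tol = 1e-5)))
    f <- fs2$field[[1]]
    zc <- f$mesh$zc
    j <- which.min(abs(zc - 0.2e-3 - 2.5e-3))
    tube2 <- pipe_spec(0.25e-3, 5e-3)
    dp2 <- pipe_pressure_for_flow(uls_to_m3s(50), tube2, alg)
    tau_num <- f$eta[50, j] * f$gamma_dot[50, j] / (f$mesh$rc[50] / 0.25e-3)
    rows$fvm_wall_shear <- abs(tau_num / pipe_wall_shear(dp2, tube2) - 1)
    tol <- c(tol, fvm_wall_shear = 0.02)
  }
  tibble::tibble(check = names(rows), error = unlist(rows),
                 tolerance = tol[names(rows)],
                 pass = unlist(rows) <= tol[names(rows)])
}
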