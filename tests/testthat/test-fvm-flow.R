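# finite-volume solver unit checks on small meshes; the full oracle
# equivalence at reference resolution lives in the acceptance suite

alg <- builtin_material("Alginate")

test_that("mesh builder reproduces the requested wall discretization", {
  g <- blunted_nozzle(0.25, 3.5, 6, 4)
  mesh <- build_mesh(g, dr = 0.005e-3, dz = 0.05e-3)
  # 50 uniform radial cells across the exit tube
  expect_equal(mesh$nfluid[length(mesh$zc)], 50)
  expect_equal(max(mesh$dr[1:50]), 0.005e-3, tolerance = 1e-12)
  # exactly one axial contraction step in the fluid-cell counts
  steps <- which(diff(mesh$nfluid) != 0)
  expect_equal(length(steps), 1)
  expect_equal(mesh$zf[steps + 1], mm_to_m(4), tolerance = 1e-12)
  # conical: monotone stepwise wall
  gc <- conical_nozzle(0.2, 2, 3.5, 6, 4)
  mc <- build_mesh(gc, dr = 0.01e-3, dz = 0.05e-3)
  expect_true(all(diff(mc$nfluid) <= 0))
  expect_error(build_mesh(g, dr = 0.1e-3), "too coarse")
})

test_that("solver reproduces the Newtonian and power-law tube solutions", {
  # short near-straight tube; oracle comparison at the fully developed
  # mid-tube station (the plug inlet needs a development length)
  g <- blunted_nozzle(0.25, 0.26, 5, 0.2)
  mesh <- build_mesh(g, dr = 0.01e-3, dz = 0.1e-3)
  tube <- pipe_spec(0.25e-3, 5e-3)
  for (mat in list(material("newt", 1000, 1, 1), alg)) {
    fs <- suppressWarnings(solve_fvm(g, mat, flow_drive(50), mesh = mesh,
      numerics = numerics_options(tol = 1e-5, max_outer = 12000)))
    f <- fs$field[[1]]
    dp_an <- pipe_pressure_for_flow(uls_to_m3s(50), tube, mat)
    zc <- f$mesh$zc
    j <- which.min(abs(zc - 0.2e-3 - 2.5e-3))
    nf <- f$mesh$nfluid[j]
    # wall-cell stress extrapolated to the wall (linear stress profile)
    tau <- f$eta[nf, j] * f$gamma_dot[nf, j] * 0.25e-3 / f$mesh$rc[nf]
    expect_equal(tau, pipe_wall_shear(dp_an, tube), tolerance = 0.04)
    # centreline velocity
    uc <- (f$u[1, j] + f$u[1, j + 1]) / 2
    expect_equal(uc, pipe_velocity_profile(f$mesh$rc[1], dp_an, tube, mat),
                 tolerance = 0.04)
  }
})

test_that("mass is conserved through every cross-section", {
  g <- blunted_nozzle(0.2, 1.0, 3, 1)
  fs <- suppressWarnings(solve_fvm(g, alg, flow_drive(20),
    mesh = build_mesh(g, dr = 0.02e-3, dz = 0.05e-3),
    numerics = numerics_options(tol = 1e-5, max_outer = 10000)))
  sf <- section_fluxes(fs$field[[1]])
  expect_lt(max(abs(sf$q_ul_s / 20 - 1)), 0.005)
  expect_equal(fs$flow_ul_s, 20, tolerance = 1e-6)
})

test_that("repeated runs are bit-identical (deterministic iteration)", {
  g <- blunted_nozzle(0.2, 0.6, 2, 0.5)
  mesh <- build_mesh(g, dr = 0.025e-3, dz = 0.1e-3)
  num <- numerics_options(tol = 1e-4, max_outer = 3000)
  f1 <- suppressWarnings(solve_fvm(g, alg, flow_drive(10), mesh = mesh,
                                   numerics = num))
  f2 <- suppressWarnings(solve_fvm(g, alg, flow_drive(10), mesh = mesh,
                                   numerics = num))
  expect_identical(f1$field[[1]]$u, f2$field[[1]]$u)
  expect_identical(f1$mss_pa, f2$mss_pa)
})

test_that("axis symmetry holds in the discrete solution", {
  g <- blunted_nozzle(0.2, 0.6, 2, 0.5)
  fs <- suppressWarnings(solve_fvm(g, alg, flow_drive(10),
    mesh = build_mesh(g, dr = 0.025e-3, dz = 0.1e-3),
    numerics = numerics_options(tol = 1e-5, max_outer = 6000)))
  f <- fs$field[[1]]
  # radial velocity vanishes on the axis; du/dr -> 0 at r = 0
  expect_true(all(abs(f$v[1, ]) == 0))
  j <- floor(length(f$mesh$zc) * 0.7)
  uc1 <- (f$u[1, j] + f$u[1, j + 1]) / 2
  uc2 <- (f$u[2, j] + f$u[2, j + 1]) / 2
  expect_lt(abs(uc2 - uc1) / uc1, 0.02)
})

test_that("pressure mode matches the imposed pressure difference", {
  g <- blunted_nozzle(0.15, 1.2, 4, 2)
  mesh <- build_mesh(g, dr = 0.015e-3, dz = 0.08e-3)
  fs <- suppressWarnings(solve_fvm(g, alg, pressure_drive(120), mesh = mesh,
    numerics = numerics_options(tol = 1e-5, max_outer = 12000)))
  expect_equal(fs$delta_p_kpa, 120, tolerance = 6e-3)
  # round trip: drive the matched flow rate, recover the pressure
  fs2 <- suppressWarnings(solve_fvm(g, alg, flow_drive(fs$flow_ul_s),
    mesh = mesh, numerics = numerics_options(tol = 1e-5, max_outer = 12000)))
  expect_equal(fs2$delta_p_kpa, fs$delta_p_kpa, tolerance = 1e-3)
})

test_that("reduced-model MSS is a lower bound on the FVM MSS", {
  cases <- list(
    list(geom = blunted_nozzle(0.15, 1.2, 4, 2), q = 30),
    list(geom = blunted_nozzle(0.25, 1.0, 6, 3), q = 60),
    list(geom = conical_nozzle(0.2, 1.0, 2.0, 4, 2), q = 150),
    list(geom = conical_nozzle(0.3, 1.5, 2.5, 6, 3), q = 300),
    list(geom = blunted_nozzle(0.35, 1.4, 5, 2), q = 120))
  for (cs in cases) {
    red <- solve_reduced(cs$geom, alg, flow_drive(cs$q))
    fvm <- suppressWarnings(solve_fvm(cs$geom, alg, flow_drive(cs$q),
      mesh = build_mesh(cs$geom, dr = cs$geom$r_small / 12, dz = 0.1e-3),
      numerics = numerics_options(tol = 1e-4, max_outer = 8000)))
    expect_gte(fvm$mss_kpa, red$mss_kpa * 0.98)
  }
})

test_that("unphysical states are rejected with diagnostics", {
  g <- blunted_nozzle(0.2, 0.6, 2, 0.5)
  mesh <- build_mesh(g, dr = 0.025e-3, dz = 0.1e-3)
  err <- tryCatch(
    suppressWarnings(solve_fvm(g, alg, flow_drive(10), mesh = mesh,
      numerics = numerics_options(tol = 1e-10, max_outer = 40))),
    error = function(e) conditionMessage(e))
  expect_match(err, "did not converge")
})

test_that("grid refinement study reports a converging table", {
  g <- blunted_nozzle(0.2, 0.6, 2, 0.5)
  tab <- suppressWarnings(grid_refinement_study(
    g, alg, flow_drive(10),
    levels = list(c(0.04e-3, 0.2e-3), c(0.02e-3, 0.1e-3), c(0.01e-3, 0.05e-3)),
    numerics = numerics_options(tol = 1e-5, max_outer = 10000)))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$converged))
  # flow-driven: the required pressure approaches a limit under refinement
  expect_lt(abs(tab$delta_p_kpa[3] - tab$delta_p_kpa[2]),
            abs(tab$delta_p_kpa[2] - tab$delta_p_kpa[1]) + 1e-9)
  # identical levels give identical results (determinism)
  tab2 <- suppressWarnings(grid_refinement_study(
    g, alg, flow_drive(10),
    levels = list(c(0.04e-3, 0.2e-3), c(0.02e-3, 0.1e-3), c(0.01e-3, 0.05e-3)),
    numerics = numerics_options(tol = 1e-5, max_outer = 10000)))
  expect_identical(tab$mss_kpa, tab2$mss_kpa)
  expect_error(grid_refinement_study(g, alg, flow_drive(10),
                                     levels = list(c(1, 1))), "3 refinement")
})
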