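alg <- builtin_material("Alginate")

test_that("kinetic-energy correction factor matches the quadrature oracle", {
  a_quad <- function(n) {
    m <- (n + 1) / n; cc <- (3 * n + 1) / (n + 1)
    2 * cc^3 * stats::integrate(function(x) (1 - x^m)^3 * x, 0, 1,
                                rel.tol = 1e-12)$value
  }
  expect_equal(alpha_energy(1), 2, tolerance = 1e-12)
  for (n in c(0.127, 0.335, 0.608, 0.9)) {
    expect_equal(alpha_energy(n), a_quad(n), tolerance = 1e-10)
  }
  expect_equal(alpha_energy(0.335), 1.545, tolerance = 1e-3)
  # plug limit
  expect_lt(alpha_energy(0.01), 1.05)
  expect_lt(alpha_energy(0.01), alpha_energy(0.3))
  expect_error(alpha_energy(0), "positive")
})

test_that("quasi-1D pressure on a straight tube matches the analytic oracle", {
  # near-degenerate blunted geometry = straight tube + negligible barrel
  geom <- blunted_nozzle(0.25, 0.2501, 10, 0.001)
  tube <- pipe_spec(0.25e-3, 10.001e-3)
  q <- uls_to_m3s(30)
  dp_num <- pressure_required(q, geom, alg, reduced_options(n_stations = 400))
  v <- q / (pi * 0.25e-3^2)
  dp_an <- pipe_pressure_for_flow(q, tube, alg) +
    alpha_energy(alg$n) * 0.5 * alg$rho * v^2 * (1 - (0.25 / 0.2501)^4)
  expect_equal(dp_num, dp_an, tolerance = 5e-3)
})

test_that("pressure_required is strictly increasing and continuous in Q", {
  geom <- conical_nozzle(0.227, 1, 3.5, 6, 4)
  qs <- uls_to_m3s(10^seq(0, 4, length.out = 40))
  dps <- pressure_required(qs, geom, alg)
  expect_true(all(diff(dps) > 0))
  # continuity: no jumps bigger than expected from the local slope
  expect_lt(max(abs(diff(log(dps)))), 0.9)
  expect_error(pressure_required(0, geom, alg), "positive")
})

test_that("pressure/flow-rate round trip inverts to 1e-6 relative", {
  geoms <- list(blunted_nozzle(0.05, 3.5, 6, 4),
                blunted_nozzle(0.42, 1.5, 20, 15),
                conical_nozzle(0.227, 1, 3.5, 6, 4),
                conical_nozzle(0.05, 3.5, 4.5, 4, 3))
  for (geom in geoms) {
    fs <- solve_reduced(geom, alg, pressure_drive(340))
    fs2 <- solve_reduced(geom, alg, flow_drive(fs$flow_ul_s))
    expect_equal(fs2$delta_p_kpa, 340, tolerance = 1e-6)
  }
})

test_that("reference-case flow summaries land in the expected bands", {
  # thin-tube blunted case: quasi-1D tracks the straight-tube solution
  fs <- solve_reduced(blunted_nozzle(0.05, 3.5, 6, 4), alg, pressure_drive(340))
  expect_gt(fs$flow_ul_s, 0.4); expect_lt(fs$flow_ul_s, 1.2)
  # conical catalogue case: required pressure near the printing pressure
  dp <- pressure_required(uls_to_m3s(3420.49),
                          conical_nozzle(0.227, 1, 3.5, 6, 4), alg)
  expect_gt(pa_to_kpa(dp), 280); expect_lt(pa_to_kpa(dp), 420)
})

test_that("flow rate decreases with consistency K at fixed pressure", {
  geom <- blunted_nozzle(0.25, 3.5, 6, 4)
  ks <- c(20, 55.7, 150)
  qs <- vapply(ks, function(k) {
    m <- material("var", rho = 1000, k = k, n = 0.335)
    solve_reduced(geom, m, pressure_drive(340))$flow_ul_s
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("MSS trends with exit radius differ between drive modes", {
  rs <- seq(0.08, 0.42, length.out = 8)
  # constant pressure: blunted MSS rises with r_small through the
  # viscosity-limited regime and stays far above the thin-tube value even
  # where the kinetic-energy limit flattens the trend
  mss_p <- vapply(rs, function(r)
    solve_reduced(blunted_nozzle(r, 3.5, 6, 4), alg,
                  pressure_drive(340))$mss_kpa, numeric(1))
  low <- rs <= 0.2
  expect_true(all(diff(mss_p[low]) > 0))
  expect_gt(min(mss_p), solve_reduced(blunted_nozzle(0.05, 3.5, 6, 4), alg,
                                      pressure_drive(340))$mss_kpa)
  # constant flow: MSS strictly decreasing in r_small
  mss_q <- vapply(rs, function(r)
    solve_reduced(blunted_nozzle(r, 3.5, 6, 4), alg,
                  flow_drive(200))$mss_kpa, numeric(1))
  expect_true(all(diff(mss_q) < 0))
})

test_that("wall profile is ordered with non-increasing pressure", {
  fs <- solve_reduced(conical_nozzle(0.2, 2, 3.5, 6, 4), alg,
                      pressure_drive(340))
  wp <- wall_profile(fs)
  expect_true(all(diff(wp$z_mm) >= 0))
  expect_true(all(diff(wp$p_kpa) <= 1e-9))
  expect_gte(fs$mss_kpa, max(wp$tau_w_kpa) - 1e-9)
  # exit mean velocity consistency
  expect_equal(fs$v_exit_m_s, fs$q_m3_s / (pi * mm_to_m(0.2)^2),
               tolerance = 1e-9)
})
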