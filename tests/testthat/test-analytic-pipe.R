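# closed-form power-law Poiseuille relations: hand-evaluated reference values
# and algebraic consistency between the individual formulas

alg <- builtin_material("Alginate")
tube <- pipe_spec(r = 0.05e-3, l = 6e-3)

test_that("wall shear stress matches the hand evaluation and its scaling", {
  expect_equal(pipe_wall_shear(kpa_to_pa(340), tube), 1416.667, tolerance = 1e-4)
  expect_equal(pipe_wall_shear(0, tube), 0)
  t2 <- pipe_spec(r = 0.05e-3, l = 12e-3)
  expect_equal(pipe_wall_shear(kpa_to_pa(340), t2),
               pipe_wall_shear(kpa_to_pa(340), tube) / 2)
  expect_error(pipe_wall_shear(-1, tube), "non-negative")
})

test_that("mean velocity matches the closed form and the Newtonian limit", {
  # frozen from an independent evaluation of the printed formula:
  # n/(3n+1) * (dp*R/(2KL))^(1/n) * R with dp=340 kPa, R=0.05 mm, L=6 mm
  expect_equal(pipe_mean_velocity(kpa_to_pa(340), tube, alg), 0.1309669,
               tolerance = 1e-6)
  mu <- 0.9
  newt <- material("newt", rho = 1000, k = mu, n = 1)
  t3 <- pipe_spec(r = 2e-4, l = 8e-3)
  dp <- 5e4
  expect_equal(pipe_mean_velocity(dp, t3, newt),
               dp * t3$r^2 / (8 * mu * t3$l), tolerance = 1e-12)
  expect_equal(pipe_mean_velocity(0, tube, alg), 0)
})

test_that("flow rate closes the system: Q = pi R^2 Vavg and the inverse", {
  v <- pipe_mean_velocity(kpa_to_pa(340), tube, alg)
  q <- pipe_flow_rate(tube, v)
  expect_equal(m3s_to_uls(q), 1.0286, tolerance = 1e-4)
  expect_equal(pipe_flow_rate(tube, 0), 0)
  # exact round trip of the closed-form inverse
  expect_equal(pipe_pressure_for_flow(q, tube, alg), kpa_to_pa(340),
               tolerance = 1e-9)
  # Newtonian Hagen-Poiseuille inverse
  newt <- material("newt", rho = 1000, k = 0.35, n = 1)
  q2 <- 2e-9
  expect_equal(pipe_pressure_for_flow(q2, tube, newt),
               8 * 0.35 * tube$l * q2 / (pi * tube$r^4), tolerance = 1e-12)
  # monotone in Q
  qs <- 10^seq(-12, -7, length.out = 20)
  expect_true(all(diff(pipe_pressure_for_flow(qs, tube, alg)) > 0))
})

test_that("velocity profile obeys no-slip and integrates to the mean velocity", {
  dp <- kpa_to_pa(340)
  expect_equal(pipe_velocity_profile(tube$r, dp, tube, alg), 0)
  # area average via quadrature (oracle) equals the closed-form mean velocity
  v_quad <- 2 / tube$r^2 * stats::integrate(function(r)
    pipe_velocity_profile(r, dp, tube, alg) * r, 0, tube$r,
    rel.tol = 1e-10)$value
  expect_equal(v_quad, pipe_mean_velocity(dp, tube, alg), tolerance = 1e-6)
  # Newtonian: parabolic with centreline twice the mean
  newt <- material("newt", rho = 1000, k = 1, n = 1)
  expect_equal(pipe_velocity_profile(0, dp, tube, newt),
               2 * pipe_mean_velocity(dp, tube, newt), tolerance = 1e-12)
  expect_error(pipe_velocity_profile(tube$r * 1.01, dp, tube, alg), "outside")
})

test_that("tau_w from pressure equals the flow-rate form (Eqs consistency)", {
  for (mat in list(alg, builtin_material("PF127"), builtin_material("AlgGel"))) {
    for (dp in c(2e4, 1e5, 3.4e5)) {
      q <- pipe_flow_rate(tube, pipe_mean_velocity(dp, tube, mat))
      expect_equal(pipe_wall_shear_at_flow(q, tube$r, mat),
                   pipe_wall_shear(dp, tube), tolerance = 1e-9)
    }
  }
})

test_that("closed forms scale correctly under geometric similarity", {
  dp <- 1e5
  for (cc in c(0.5, 2, 7)) {
    scaled <- pipe_spec(tube$r * cc, tube$l * cc)
    # tau_w invariant under R->cR, L->cL
    expect_equal(pipe_wall_shear(dp, scaled), pipe_wall_shear(dp, tube))
    # Vavg scales with R at fixed dp*R/(2KL) => V ~ c
    expect_equal(pipe_mean_velocity(dp, scaled, alg),
                 cc * pipe_mean_velocity(dp, tube, alg), tolerance = 1e-12)
  }
})
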