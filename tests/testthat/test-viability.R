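test_that("packaged study fixture is intact digit for digit", {
  path <- system.file("extdata", "viability_studies.csv", package = "nozzleflow")
  expect_identical(unname(tools::md5sum(path)),
                   "53f8189e5cb0ffedace0a607c539c25c")
  st <- builtin_studies()
  expect_equal(nrow(st), 10)
  expect_equal(sum(st$incomplete), 2)
  # spot checks against the printed rows
  r4 <- st[4, ]
  expect_equal(r4$k, 10.82); expect_equal(r4$n, 0.54)
  expect_equal(r4$l_lower_mm, 20)
  expect_equal(c(r4$flow_lo_uls, r4$flow_hi_uls), c(2.3, 12.6))
  expect_equal(c(r4$mss_lo_kpa, r4$mss_hi_kpa), c(0.68, 1.708))
  expect_true(all(st$viability_lo_pct >= 0 & st$viability_hi_pct <= 100,
                  na.rm = TRUE))
  expect_true(all(st$viability_lo_pct <= st$viability_hi_pct, na.rm = TRUE))
})

test_that("the printed nozzle-size column is read as a diameter by default", {
  st <- builtin_studies()
  expect_equal(st$r_small_lo_mm, st$rs_col_lo_mm / 2)
  st2 <- builtin_studies(rs_is_diameter = FALSE)
  expect_equal(st2$r_small_lo_mm, st2$rs_col_lo_mm)
})

test_that("incomplete or drive-less records are flagged non-simulatable", {
  st <- builtin_studies()
  expect_false(any(st$simulatable[st$incomplete]))
  expect_equal(sum(st$simulatable), 8)
})

test_that("study endpoints reproduce stress ranges and the 2D control", {
  st <- builtin_studies()
  pts <- suppressMessages(simulate_records(st, solver = "reduced"))
  expect_true(all(is.finite(pts$mss_kpa)))
  # zero-pressure endpoints are 2D controls at exactly zero stress
  zero <- pts[pts$drive_var == "pressure_kpa" & pts$drive_value == 0, ]
  expect_gt(nrow(zero), 0)
  expect_true(all(zero$mss_kpa == 0))
  # within a study the higher drive endpoint carries the higher stress
  by_study <- split(pts, pts$study)
  for (d in by_study) {
    if (nrow(d) == 2) expect_lte(d$mss_kpa[d$endpoint == "low"],
                                 d$mss_kpa[d$endpoint == "high"])
  }
  # fully developed wall stress tracks the printed low endpoints where the
  # low-shear regime makes corner concentration negligible (flow-driven rows)
  l8 <- pts[grepl("B40", pts$study) & pts$endpoint == "low", ]
  expect_equal(l8$mss_kpa, l8$mss_reported_kpa, tolerance = 0.15)
})

test_that("stress-viability association is negative for stem-cell studies", {
  st <- builtin_studies()
  pts <- suppressMessages(simulate_records(st, solver = "reduced"))
  assoc <- viability_association(pts)
  pooled <- assoc$pooled
  expect_lt(pooled$spearman[pooled$group == "stem_cells"], 0)
  # synthetic degenerate studies: flat and strictly decreasing
  synth <- tibble::tibble(
    study = rep(c("flat", "down"), each = 4),
    cell = "synthetic",
    mss_kpa = rep(1:4, 2),
    viability_pct = c(90, 90, 90, 90, 95, 80, 60, 40))
  a2 <- viability_association(synth)
  expect_equal(a2$per_study$spearman[a2$per_study$study == "down"], -1)
  expect_equal(a2$per_study$trend[a2$per_study$study == "flat"], "flat")
  # constant viability has no rank variance: correlation is undefined (NA)
  expect_true(is.na(a2$per_study$spearman[a2$per_study$study == "flat"]))
})

test_that("constant-flow sweep gives strictly decreasing MSS with diameter", {
  alg <- builtin_material("Alginate")
  sw <- constant_flow_diameter_sweep(alg, flow_uls = 200,
                                     diameters_mm = c(0.15, 0.3, 0.5, 0.8))
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$mss_kpa) < 0))
  # doubling the flow rate at fixed diameter raises the stress
  sw2 <- constant_flow_diameter_sweep(alg, flow_uls = 400,
                                      diameters_mm = c(0.15, 0.3, 0.5, 0.8))
  expect_true(all(sw2$mss_kpa > sw$mss_kpa))
  # single diameter
  sw1 <- constant_flow_diameter_sweep(alg, 200, diameters_mm = 0.4)
  expect_equal(nrow(sw1), 1)
  expect_error(constant_flow_diameter_sweep(alg, 200, diameters_mm = 2),
               "range")
})

test_that("pressure-driven MSS is monotone in pressure for fixture geometries", {
  st <- builtin_studies()
  rec <- st[st$simulatable & !is.na(st$pressure_lo_kpa), ][1, ]
  mat <- material(rec$material, 1000, rec$k, rec$n)
  geom <- blunted_nozzle(rec$r_small_lo_mm, 3.5, rec$l_lower_mm, 4)
  mss <- vapply(c(50, 120, 275), function(p)
    solve_reduced(geom, mat, pressure_drive(p))$mss_kpa, numeric(1))
  expect_true(all(diff(mss) > 0))
})
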