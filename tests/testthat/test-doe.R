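test_that("LHS projections are stratified and reproducible", {
  for (shape in c("blunted", "conical")) {
    n <- 60
    d1 <- lhs_design(shape, n = n, seed = 7)
    d2 <- lhs_design(shape, n = n, seed = 7)
    expect_identical(d1, d2)  # bit-exact under the same seed
    d3 <- lhs_design(shape, n = n, seed = 8)
    expect_false(isTRUE(all.equal(d1, d3)))
    rng <- parameter_ranges(shape)
    for (k in seq_len(nrow(rng))) {
      v <- d1[[rng$parameter[k]]]
      u <- (v - rng$low[k]) / (rng$high[k] - rng$low[k])
      expect_true(all(u >= 0 & u <= 1))
      # one point per equal-probability bin
      expect_equal(sort(unique(floor(u * n - 1e-12))), 0:(n - 1))
    }
  }
})

test_that("conical designs all satisfy the exclusion constraint", {
  d <- lhs_design("conical", n = 200, seed = 3)
  expect_equal(nrow(d), 200)
  expect_true(all(d$r_big_mm > d$r_middle_mm))
  # stratification survives the constraint repair
  rng <- parameter_ranges("conical")
  for (p in c("r_big_mm", "r_middle_mm")) {
    k <- match(p, rng$parameter)
    u <- (d[[p]] - rng$low[k]) / (rng$high[k] - rng$low[k])
    expect_equal(sort(unique(floor(u * 200 - 1e-12))), 0:199)
  }
})

test_that("campaigns evaluate every design and tolerate row order", {
  alg <- builtin_material("Alginate")
  d <- lhs_design("blunted", n = 24, seed = 5)
  resp <- run_campaign(d, alg, pressure_drive(340), solver = "reduced")
  expect_equal(nrow(resp), 24)
  expect_true(all(resp$ok))
  expect_true(all(is.finite(resp$mss_kpa)))
  # permutation invariance of the summary
  s1 <- summarize_campaign(resp)
  s2 <- summarize_campaign(resp[sample(24), ])
  expect_equal(s1, s2)
  # single-row campaign
  r1 <- run_campaign(d[3, ], alg, pressure_drive(340))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$mss_kpa, resp$mss_kpa[3])
})

test_that("campaign summary has zero IQR for a constant column", {
  resp <- tibble::tibble(mss_kpa = rep(2.5, 10), flow_ul_s = runif(10),
                         nu_exit_m2_s = runif(10), ok = TRUE)
  s <- summarize_campaign(resp)
  row <- s[s$response == "mss_kpa", ]
  expect_equal(row$q3 - row$q1, 0)
  expect_equal(row$min, row$max)
  expect_error(summarize_campaign(resp[0, ]), "empty")
})

test_that("conical campaigns reach higher stress and flow than blunted", {
  alg <- builtin_material("Alginate")
  db <- lhs_design("blunted", n = 40, seed = 11)
  dc <- lhs_design("conical", n = 40, seed = 11)
  rb <- run_campaign(db, alg, pressure_drive(340))
  rc <- run_campaign(dc, alg, pressure_drive(340))
  expect_gt(max(rc$mss_kpa), max(rb$mss_kpa))
  expect_gt(stats::median(rc$flow_ul_s), stats::median(rb$flow_ul_s))
})

test_that("shear-thinning sweep reproduces the shape-dependent trends", {
  # conical, fixed exit radius: MSS increases with r_middle for every n
  sw <- shear_thinning_sweep("conical", sweep = "r_middle",
                             values = seq(1, 3.4, length.out = 6),
                             n_values = c(0.1, 0.4, 0.75))
  for (nv in unique(sw$n)) {
    expect_true(all(diff(sw$mss_kpa[sw$n == nv]) > 0))
  }
  # constant-pressure blunted sweep: MSS increases with r_small in the
  # viscosity-limited regime (small exit radii)
  swb <- shear_thinning_sweep("blunted", sweep = "r_small",
                              values = seq(0.06, 0.2, length.out = 5),
                              n_values = c(0.4, 0.75))
  for (nv in unique(swb$n)) {
    expect_true(all(diff(swb$mss_kpa[swb$n == nv]) > -1e-9))
  }
  expect_error(shear_thinning_sweep("blunted", sweep = "r_middle"), "conical")
  expect_error(shear_thinning_sweep("conical", n_values = c(0.5, 1.2)),
               "indices")
})
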