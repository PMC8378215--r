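# synthetic-function oracles for the GP surrogate and the variance-based
# sensitivity machinery

make_lhs_unit <- function(n, d, seed) {
  set.seed(seed)
  lhs::randomLHS(n, d) * 2 - 1  # scaled to [-1, 1]
}

test_that("ARD length scales separate active from inert inputs", {
  x <- make_lhs_unit(60, 2, 1)
  colnames(x) <- c("x1", "x2")
  y <- sin(2.5 * x[, 1])  # nonlinear in x1, x2 inert
  gp <- fit_gp(x, y, ranges = cbind(low = c(-1, -1), high = c(1, 1)))
  expect_gt(gp$lengthscales["x2"] / gp$lengthscales["x1"], 5)
  # interpolation at training points within nugget-consistent error
  pr <- predict(gp, x, scaled = TRUE)
  expect_lt(max(abs(pr$mean - y)), 3 * gp$sigma_n * gp$y_sd + 1e-5)
  # a purely linear active input still leaves the inert input flat
  gp2 <- fit_gp(x, x[, 1], ranges = cbind(low = c(-1, -1), high = c(1, 1)))
  me2 <- main_effect(gp2, 2, n_mc = 1500, seed = 1)
  expect_lt(max(abs(me2$effect)), 0.05)
})

test_that("constant responses are fitted as constants with a warning", {
  x <- make_lhs_unit(20, 3, 2)
  expect_warning(gp <- fit_gp(x, rep(4.2, 20)), "zero variance")
  pr <- predict(gp, matrix(0, 2, 3), scaled = TRUE)
  expect_equal(pr$mean, c(4.2, 4.2))
})

test_that("predictive intervals are symmetric and widen away from data", {
  x <- make_lhs_unit(40, 2, 3)
  y <- sin(2 * x[, 1]) + 0.5 * x[, 2]
  gp <- fit_gp(x, y)
  near <- predict(gp, x[1:5, , drop = FALSE], scaled = TRUE)
  expect_equal(near$ci90_high - near$mean, near$mean - near$ci90_low)
  expect_equal(near$ci90_high - near$mean, 1.645 * near$sd)
  far <- suppressWarnings(predict(gp, matrix(c(1.04, 1.04), 1), scaled = TRUE))
  expect_gt(far$sd, min(near$sd))
  expect_warning(predict(gp, matrix(c(1.04, 0), 1), scaled = TRUE),
                 "extrapolation")
  expect_error(predict(gp, matrix(c(1.2, 0), 1), scaled = TRUE), "far outside")
})

test_that("main effects recover an additive decomposition", {
  x <- make_lhs_unit(80, 2, 4)
  f1 <- function(z) z; f2 <- function(z) z^2
  y <- f1(x[, 1]) + f2(x[, 2])
  gp <- fit_gp(x, y)
  me1 <- main_effect(gp, 1, grid_size = 11, n_mc = 3000, seed = 1)
  me2 <- main_effect(gp, 2, grid_size = 11, n_mc = 3000, seed = 1)
  # centred truths on the grid, in the standardized response units the
  # effect curves are reported in
  g <- me1$x_scaled
  y_sd <- gp$y_sd
  expect_lt(max(abs(me1$effect - (g - mean(g)) / y_sd)), 0.12)
  truth2 <- (g^2 - mean(g^2)) / y_sd
  expect_lt(max(abs(me2$effect - truth2)), 0.12)
  expect_true(all(me1$ci90_low <= me1$effect & me1$effect <= me1$ci90_high))
})

test_that("inert parameters give flat main effects and near-zero indices", {
  x <- make_lhs_unit(70, 3, 5)
  y <- 2 * x[, 1]
  gp <- fit_gp(x, y)
  me3 <- main_effect(gp, 3, n_mc = 2000, seed = 2)
  expect_lt(max(abs(me3$effect)), 0.05 * diff(range(y)))
  sens <- sobol_indices(gp, n_base = 1024, seed = 1, n_boot = 50)
  expect_lt(sens$s_total[2], 0.05)
  expect_lt(sens$s_total[3], 0.05)
  expect_gt(sens$s_total[1], 0.9)
})

test_that("Sobol indices match the closed-form variance decomposition", {
  # y = x1 + 2 x2, uniform on [-1,1]^2: V1 = 1/3, V2 = 4/3 => S = (0.2, 0.8)
  x <- make_lhs_unit(120, 2, 6)
  y <- x[, 1] + 2 * x[, 2]
  gp <- fit_gp(x, y)
  sens <- sobol_indices(gp, n_base = 4096, seed = 3, n_boot = 100)
  expect_equal(sens$s_first, c(0.2, 0.8), tolerance = 0.05)
  expect_equal(sens$s_total, c(0.2, 0.8), tolerance = 0.05)
  # first order <= total (within estimator noise)
  expect_true(all(sens$s_first <= sens$s_total + 0.05))
  # bootstrap columns present for the box plots
  expect_equal(nrow(sens$boot[[1]]), 100)
})

test_that("index estimator converges on an interaction function", {
  # Ishigami-like on [-1,1]: y = sin(pi x1) + 7 sin(pi x2)^2
  #   + 0.1 (pi x3)^4 sin(pi x1)
  f <- function(x) sin(pi * x[, 1]) + 7 * sin(pi * x[, 2])^2 +
    0.1 * (pi * x[, 3])^4 * sin(pi * x[, 1])
  # analytic first-order indices of the Ishigami function (a=7, b=0.1)
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- V1 + V2 + (8 * b^2 * pi^8 / 225)
  x <- make_lhs_unit(300, 3, 7)
  gp <- fit_gp(x, f(x))
  errs <- vapply(c(10, 12), function(pw) {
    s <- sobol_indices(gp, n_base = 2^pw, seed = 5, n_boot = 10)
    max(abs(s$s_first[1:2] - c(V1 / V, V2 / V)))
  }, numeric(1))
  expect_lt(errs[2], 0.1)  # surrogate + MC error at the larger sample
})

test_that("parameter ranking flags negligible inputs with stable ties", {
  sens <- tibble::tibble(parameter = c("a", "b", "c"),
                         s_first = c(0.5, 0.02, 0.02),
                         s_total = c(0.6, 0.03, 0.03))
  rk <- rank_parameters(sens)
  expect_equal(rk$parameter, c("a", "b", "c"))  # tie broken by declaration
  expect_equal(rk$negligible, c(FALSE, TRUE, TRUE))
})

test_that("campaign surrogate classifies geometry drivers as reported", {
  alg <- builtin_material("Alginate")
  d <- lhs_design("blunted", n = 120, seed = 21)
  resp <- run_campaign(d, alg, pressure_drive(340), solver = "reduced")
  pars <- c("r_small_mm", "r_big_mm", "l_lower_mm", "l_upper_mm")
  rng <- parameter_ranges("blunted")
  gp <- fit_gp(resp[pars], log(resp$mss_kpa), ranges = rng)
  sens <- sobol_indices(gp, n_base = 2048, seed = 2, n_boot = 50)
  st <- stats::setNames(sens$s_total, sens$parameter)
  expect_lt(st[["r_big_mm"]], 0.05)
  expect_lt(st[["l_upper_mm"]], 0.05)
  expect_gt(st[["r_small_mm"]], 0.1)
  expect_gt(st[["l_lower_mm"]], 0.05)
  # held-out accuracy: the response is smooth in geometry
  set.seed(9)
  test_idx <- sample(120, 24)
  gp2 <- fit_gp(resp[pars][-test_idx, ], log(resp$mss_kpa)[-test_idx],
                ranges = rng)
  pr <- predict(gp2, resp[pars][test_idx, ])
  r2 <- 1 - sum((pr$mean - log(resp$mss_kpa)[test_idx])^2) /
    sum((log(resp$mss_kpa)[test_idx] - mean(log(resp$mss_kpa)[test_idx]))^2)
  expect_gt(r2, 0.9)
})

test_that("split-half stability of the negligible/active classification", {
  alg <- builtin_material("Alginate")
  d <- lhs_design("blunted", n = 160, seed = 31)
  resp <- run_campaign(d, alg, pressure_drive(340), solver = "reduced")
  pars <- c("r_small_mm", "r_big_mm", "l_lower_mm", "l_upper_mm")
  rng <- parameter_ranges("blunted")
  set.seed(13)
  half <- sample(160, 80)
  cls <- lapply(list(half, setdiff(1:160, half)), function(idx) {
    gp <- fit_gp(resp[pars][idx, ], log(resp$mss_kpa)[idx], ranges = rng)
    s <- sobol_indices(gp, n_base = 2048, seed = 4, n_boot = 20)
    rank_parameters(s)$negligible[order(rank_parameters(s)$parameter)]
  })
  expect_identical(cls[[1]], cls[[2]])
})

test_that("tidy and glance expose the surrogate in broom style", {
  x <- make_lhs_unit(30, 2, 8)
  gp <- fit_gp(x, x[, 1] + x[, 2]^2)
  td <- tidy(gp)
  expect_equal(names(td), c("parameter", "lengthscale", "relevance"))
  gl <- glance(gp)
  expect_equal(gl$n, 30)
  expect_false(gl$constant)
})
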