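#' Fit a Gaussian-process surrogate with ARD kernel
#'
#' Fits a stationary anisotropic (automatic-relevance-determination)
#' squared-exponential Gaussian process to a design matrix and a scalar
#' response. Inputs are scaled to \eqn{[-1,1]} per parameter and the response
#' is centered and scaled, so main-effect curves and sensitivities of
#' different campaigns are directly comparable. Hyperparameters (one length
#' scale per input, signal variance, nugget) maximize the log marginal
#' likelihood plus weak log-normal priors (MAP), with multi-start L-BFGS-B
#' optimization under a fixed seed.
#'
#' @param x data frame or matrix of inputs (>= 10 rows). Duplicated rows
#'   (after scaling) are collapsed with their responses averaged.
#' @param y numeric response vector.
#' @param ranges optional two-column matrix / data frame (`low`, `high`, one
#'   row per input, rownames or `parameter` column matching `colnames(x)`)
#'   used for the \eqn{[-1,1]} scaling; defaults to the observed ranges.
#' @param restarts number of optimizer restarts (>= 1).
#' @param seed RNG seed for the restarts.
#' @return an object of class `gp_surrogate`.
#' @export
fit_gp <- function(x, y, ranges = NULL, restarts = 5, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 10) stop("need at least 10 rows to fit the surrogate", call. = FALSE)
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(ranges)) {
    ranges <- cbind(low = apply(x, 2, min), high = apply(x, 2, max))
  } else {
    ranges <- .as_ranges(ranges, colnames(x))
  }
  if (any(ranges[, 2] <= ranges[, 1]))
    stop("degenerate input ranges", call. = FALSE)
  xs <- .scale_pm1(x, ranges)

  # collapse duplicates (averaged response)
  key <- apply(round(xs, 12), 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    agg <- tapply(y, key, mean)
    keep <- !duplicated(key)
    xs <- xs[keep, , drop = FALSE]
    y <- as.numeric(agg[key[keep]])
  }

  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12 * (abs(y_mean) + 1)) {
    warning("response has (near-)zero variance; fitting a constant surrogate",
            call. = FALSE)
    gp <- structure(list(constant = TRUE, y_mean = y_mean, y_sd = 1,
                         x = xs, ranges = ranges, parameters = colnames(x)),
                    class = "gp_surrogate")
    return(gp)
  }
  ys <- (y - y_mean) / y_sd
  d <- ncol(xs); n <- nrow(xs)

  # theta = c(log ell_1..d, log sigma_f, log sigma_n)
  neg_map <- function(theta) {
    val <- .gp_nlml(theta, xs, ys)
    if (!is.finite(val)) return(1e10)
    lell <- theta[1:d]; lsf <- theta[d + 1]; lsn <- theta[d + 2]
    # weak log-normal priors keep the optimum away from degenerate corners
    val + sum((lell - log(1))^2 / (2 * 1.5^2)) +
      (lsf - 0)^2 / (2 * 1.5^2) + (lsn - log(1e-2))^2 / (2 * 3^2)
  }
  lower <- c(rep(log(5e-2), d), log(1e-3), log(1e-6))
  upper <- c(rep(log(50), d), log(50), log(1))
  set.seed(as.integer(seed))
  starts <- lapply(seq_len(max(1, restarts)), function(i) {
    if (i == 1) c(rep(log(1), d), 0, log(1e-2))
    else stats::runif(d + 2, lower + 0.5, upper - 0.5)
  })
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, neg_map, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 200)),
             error = function(e) list(value = Inf))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (!is.finite(best$value)) stop("GP hyperparameter optimization failed", call. = FALSE)
  theta <- best$par
  ell <- exp(theta[1:d]); sf <- exp(theta[d + 1]); sn <- exp(theta[d + 2])

  K <- .gp_kernel(xs, xs, ell, sf)
  ch <- .chol_jitter(K + diag(sn^2, n))
  alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
  structure(list(constant = FALSE, x = xs, y_scaled = ys,
                 y_mean = y_mean, y_sd = y_sd, ranges = ranges,
                 parameters = colnames(x),
                 lengthscales = stats::setNames(ell, colnames(x)),
                 sigma_f = sf, sigma_n = sn,
                 chol = ch, alpha = alpha,
                 log_marginal = -.gp_nlml(theta, xs, ys)),
            class = "gp_surrogate")
}

.as_ranges <- function(ranges, pars) {
  if (is.data.frame(ranges) && all(c("parameter", "low", "high") %in% names(ranges))) {
    m <- as.matrix(ranges[, c("low", "high")])
    rownames(m) <- ranges$parameter
    ranges <- m
  }
  ranges <- as.matrix(ranges)
  if (!is.null(rownames(ranges))) ranges <- ranges[pars, , drop = FALSE]
  if (nrow(ranges) != length(pars)) stop("ranges do not match inputs", call. = FALSE)
  colnames(ranges) <- c("low", "high")
  ranges
}

.scale_pm1 <- function(x, ranges) {
  mid <- (ranges[, 1] + ranges[, 2]) / 2
  half <- (ranges[, 2] - ranges[, 1]) / 2
  sweep(sweep(x, 2, mid, `-`), 2, half, `/`)
}

.gp_kernel <- function(xa, xb, ell, sf) {
  d2 <- matrix(0, nrow(xa), nrow(xb))
  for (j in seq_along(ell)) {
    d2 <- d2 + outer(xa[, j] / ell[j], xb[, j] / ell[j], `-`)^2
  }
  sf^2 * exp(-0.5 * d2)
}

.chol_jitter <- function(A) {
  jit <- 0
  for (i in 0:8) {
    ch <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jit <- if (jit == 0) 1e-10 else jit * 10
  }
  stop("covariance matrix not positive definite even after jitter escalation",
       call. = FALSE)
}

.gp_nlml <- function(theta, xs, ys) {
  d <- ncol(xs); n <- nrow(xs)
  ell <- exp(theta[1:d]); sf <- exp(theta[d + 1]); sn <- exp(theta[d + 2])
  K <- .gp_kernel(xs, xs, ell, sf) + diag(sn^2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  a <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
  0.5 * sum(ys * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' @export
print.gp_surrogate <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("<gp_surrogate> constant response, mean =", x$y_mean, "\n")
    return(invisible(x))
  }
  cat(sprintf("<gp_surrogate> %d points, %d inputs; sigma_f = %.3g, nugget = %.3g\n",
              nrow(x$x), length(x$lengthscales), x$sigma_f, x$sigma_n))
  cat("  length-scales:",
      paste(sprintf("%s=%.3g", names(x$lengthscales), x$lengthscales),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a Gaussian-process surrogate
#'
#' @param object a [fit_gp()] surrogate.
#' @param newdata data frame / matrix in original units, or a matrix already
#'   scaled to \eqn{[-1,1]} when `scaled = TRUE`.
#' @param scaled whether `newdata` is already in scaled coordinates.
#' @param ... unused.
#' @return a tibble with `mean`, `sd`, `ci90_low`, `ci90_high` on the original
#'   response scale (the 90% interval is mean ± 1.645 predictive sd, nugget
#'   included).
#' @export
predict.gp_surrogate <- function(object, newdata, scaled = FALSE, ...) {
  xnew <- as.matrix(newdata)
  if (!scaled) xnew <- .scale_pm1(xnew, object$ranges)
  if (any(abs(xnew) > 1.05 + 1e-9))
    stop("prediction point far outside the design region (|scaled x| > 1.05)",
         call. = FALSE)
  if (any(abs(xnew) > 1 + 1e-9))
    warning("slight extrapolation beyond the design region", call. = FALSE)
  if (isTRUE(object$constant)) {
    return(tibble::tibble(mean = rep(object$y_mean, nrow(xnew)), sd = 0,
                          ci90_low = object$y_mean, ci90_high = object$y_mean))
  }
  ks <- .gp_kernel(xnew, object$x, object$lengthscales, object$sigma_f)
  mu <- as.numeric(ks %*% object$alpha)
  v <- backsolve(object$chol, t(ks), transpose = TRUE)
  var_lat <- pmax(object$sigma_f^2 - colSums(v^2), 0)
  sd_pred <- sqrt(var_lat + object$sigma_n^2) * object$y_sd
  mu <- mu * object$y_sd + object$y_mean
  tibble::tibble(mean = mu, sd = sd_pred,
                 ci90_low = mu - 1.645 * sd_pred,
                 ci90_high = mu + 1.645 * sd_pred)
}

# predictive mean only, scaled coords in, scaled response out (fast path for
# Monte-Carlo sensitivity sweeps)
.gp_mean_scaled <- function(gp, xs) {
  if (isTRUE(gp$constant)) return(rep(0, nrow(xs)))
  ks <- .gp_kernel(xs, gp$x, gp$lengthscales, gp$sigma_f)
  as.numeric(ks %*% gp$alpha)
}

#' Main-effect curve of one input
#'
#' The averaged model response as one input sweeps its range while all other
#' inputs are integrated out under the independent uniform measure on
#' \eqn{[-1,1]^{d}}: a Monte-Carlo average of the GP predictive mean using
#' common random draws across the grid, centered to zero over the grid.
#' On the plot axes, scaled coordinate 0 is the middle of the parameter
#' range and -1/+1 its limits.
#'
#' @param gp a [fit_gp()] surrogate.
#' @param parameter input name or index.
#' @param grid_size number of grid points over \eqn{[-1,1]}.
#' @param n_mc Monte-Carlo draws of the remaining inputs (>= 2000 by default).
#' @param seed RNG seed.
#' @return a `main_effect` tibble with `parameter`, `x_scaled`, `x`, `effect`
#'   (centered, scaled-response units), `ci90_low`, `ci90_high`.
#' @export
main_effect <- function(gp, parameter, grid_size = 21, n_mc = 2000, seed = 1) {
  stopifnot(inherits(gp, "gp_surrogate"))
  j <- if (is.character(parameter)) match(parameter, gp$parameters) else parameter
  if (is.na(j) || j < 1 || j > length(gp$parameters))
    stop("unknown parameter", call. = FALSE)
  d <- length(gp$parameters)
  set.seed(as.integer(seed))
  zother <- matrix(stats::runif(n_mc * d, -1, 1), n_mc, d)
  grid <- seq(-1, 1, length.out = grid_size)
  eff <- numeric(grid_size); sdm <- numeric(grid_size)
  for (g in seq_along(grid)) {
    z <- zother; z[, j] <- grid[g]
    if (isTRUE(gp$constant)) { eff[g] <- 0; sdm[g] <- 0; next }
    ks <- .gp_kernel(z, gp$x, gp$lengthscales, gp$sigma_f)
    mu <- as.numeric(ks %*% gp$alpha)
    v <- backsolve(gp$chol, t(ks), transpose = TRUE)
    eff[g] <- mean(mu)
    # posterior sd of the conditional mean, approximated by the average
    # latent predictive sd of the Monte-Carlo sample
    sdm[g] <- mean(sqrt(pmax(gp$sigma_f^2 - colSums(v^2), 0)))
  }
  eff <- eff - mean(eff)
  half <- (gp$ranges[j, 2] - gp$ranges[j, 1]) / 2
  mid <- (gp$ranges[j, 1] + gp$ranges[j, 2]) / 2
  out <- tibble::tibble(parameter = gp$parameters[j], x_scaled = grid,
                        x = mid + half * grid, effect = eff,
                        ci90_low = eff - 1.645 * sdm,
                        ci90_high = eff + 1.645 * sdm)
  class(out) <- c("main_effect", class(out))
  out
}

#' Main effects of all inputs
#' @inheritParams main_effect
#' @export
main_effects <- function(gp, grid_size = 21, n_mc = 2000, seed = 1) {
  out <- purrr::map(gp$parameters, main_effect, gp = gp, grid_size = grid_size,
                    n_mc = n_mc, seed = seed)
  out <- dplyr::bind_rows(out)
  class(out) <- c("main_effect", class(out))
  out
}

#' Variance-based (Sobol) sensitivity indices of the surrogate
#'
#' First-order and total indices of the GP predictive mean under independent
#' uniform inputs on \eqn{[-1,1]^d}, using the Saltelli pick-freeze scheme
#' with the Jansen total-effect estimator. A bootstrap over the Monte-Carlo
#' rows supplies the sampling distribution shown in the sensitivity box
#' plots.
#'
#' @param gp a [fit_gp()] surrogate.
#' @param n_base base sample size (>= 1024).
#' @param seed RNG seed.
#' @param n_boot bootstrap resamples (>= 100 for the box-plot distribution).
#' @return a `sensitivity_result` tibble with one row per parameter:
#'   `s_first`, `s_total`, their bootstrap quartiles, and the bootstrap
#'   draws in the `boot` list-column.
#' @export
sobol_indices <- function(gp, n_base = 2048, seed = 1, n_boot = 100) {
  stopifnot(inherits(gp, "gp_surrogate"))
  if (n_base < 64) stop("n_base too small", call. = FALSE)
  d <- length(gp$parameters)
  set.seed(as.integer(seed))
  A <- matrix(stats::runif(n_base * d, -1, 1), n_base, d)
  B <- matrix(stats::runif(n_base * d, -1, 1), n_base, d)
  fA <- .gp_mean_scaled(gp, A)
  fB <- .gp_mean_scaled(gp, B)
  fAB <- matrix(0, n_base, d)
  for (j in seq_len(d)) {
    ABj <- A; ABj[, j] <- B[, j]
    fAB[, j] <- .gp_mean_scaled(gp, ABj)
  }
  est <- function(idx) {
    a <- fA[idx]; b <- fB[idx]
    V <- stats::var(c(a, b))
    if (V <= 0) return(list(s = rep(0, d), st = rep(0, d)))
    s <- vapply(seq_len(d), function(j)
      mean(b * (fAB[idx, j] - a)) / V, numeric(1))
    st <- vapply(seq_len(d), function(j)
      0.5 * mean((a - fAB[idx, j])^2) / V, numeric(1))
    list(s = s, st = st)
  }
  point <- est(seq_len(n_base))
  boot_s <- matrix(NA_real_, n_boot, d)
  boot_st <- matrix(NA_real_, n_boot, d)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_base, n_base, replace = TRUE)
    eb <- est(idx)
    boot_s[b, ] <- eb$s; boot_st[b, ] <- eb$st
  }
  out <- tibble::tibble(
    parameter = gp$parameters,
    s_first = point$s,
    s_total = point$st,
    s_first_q1 = apply(boot_s, 2, stats::quantile, 0.25),
    s_first_q3 = apply(boot_s, 2, stats::quantile, 0.75),
    s_total_q1 = apply(boot_st, 2, stats::quantile, 0.25),
    s_total_q3 = apply(boot_st, 2, stats::quantile, 0.75),
    boot = purrr::map(seq_len(d), function(j)
      tibble::tibble(s_first = boot_s[, j], s_total = boot_st[, j]))
  )
  attr(out, "n_base") <- n_base
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Rank inputs by total sensitivity
#'
#' @param sens a [sobol_indices()] result.
#' @param negligible_below total-index threshold under which an input is
#'   flagged negligible (default 0.05).
#' @return the sensitivity tibble ordered by decreasing total index (ties
#'   broken by declaration order) with `rank` and `negligible` columns.
#' @export
rank_parameters <- function(sens, negligible_below = 0.05) {
  ord <- order(-sens$s_total, seq_len(nrow(sens)))
  out <- sens[ord, ]
  out$rank <- seq_len(nrow(out))
  out$negligible <- out$s_total < negligible_below
  out
}
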