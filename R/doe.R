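#' Default nozzle-parameter ranges (mm)
#'
#' The commercially available print-nozzle ranges used for the
#' design-of-experiments box: `r_small` 0.05–0.42, `r_middle` 1–3.5 (conical
#' only), `r_big` 1.5–4.5, `l_lower` 4–20, `l_upper` 3–15 mm.
#'
#' @param shape `"blunted"` (4 parameters) or `"conical"` (5 parameters).
#' @return a tibble with columns `parameter`, `low`, `high` (mm).
#' @export
parameter_ranges <- function(shape = c("blunted", "conical")) {
  shape <- match.arg(shape)
  tb <- tibble::tribble(
    ~parameter,    ~low, ~high,
    "r_small_mm",  0.05, 0.42,
    "r_middle_mm", 1.0,  3.5,
    "r_big_mm",    1.5,  4.5,
    "l_lower_mm",  4.0,  20.0,
    "l_upper_mm",  3.0,  15.0
  )
  if (shape == "blunted") tb <- tb[tb$parameter != "r_middle_mm", ]
  tb
}

#' Constrained maximin Latin-hypercube nozzle design
#'
#' Generates `n` nozzle designs by Latin-hypercube sampling over the parameter
#' box, with every one-dimensional projection stratified (one value per
#' equal-probability bin per parameter). The space-filling candidate is chosen
#' as the best of 50 random Latin hypercubes under the maximin
#' (largest-minimal-pairwise-distance) criterion. For conical nozzles the
#' geometric constraint `r_big > r_middle` is enforced by re-pairing the
#' realized `r_big` values against `r_middle` (random greedy matching), which
#' keeps every marginal stratified projection intact rather than discarding
#' whole designs. Deterministic given `seed`.
#'
#' @param shape `"blunted"` or `"conical"`.
#' @param n number of designs (>= 2; 200 is the campaign default).
#' @param seed integer RNG seed.
#' @param ranges parameter ranges as from [parameter_ranges()].
#' @param n_candidates number of random LHS candidates scored by the maximin
#'   criterion.
#' @return a tibble of `n` designs (mm columns) with attributes `seed` and
#'   `shape`; every row satisfies [validate_geometry()].
#' @export
#' @examples
#' lhs_design("conical", n = 20, seed = 1)
lhs_design <- function(shape = c("blunted", "conical"), n = 200, seed = 1,
                       ranges = parameter_ranges(shape), n_candidates = 50) {
  shape <- match.arg(shape)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  pars <- ranges$parameter
  k <- length(pars)
  set.seed(as.integer(seed))
  # maximin over random LHS candidates (distances in unit-cube coordinates)
  best <- NULL; best_score <- -Inf
  for (cand in seq_len(n_candidates)) {
    u <- lhs::randomLHS(n, k)
    score <- min(stats::dist(u))
    if (score > best_score) { best_score <- score; best <- u }
  }
  u <- best
  colnames(u) <- pars
  if (shape == "conical") u <- .repair_conical(u, ranges, n)
  x <- sweep(sweep(u, 2, ranges$high - ranges$low, `*`), 2, ranges$low, `+`)
  out <- tibble::as_tibble(as.data.frame(x))
  out <- dplyr::mutate(out, design_id = dplyr::row_number(), .before = 1)
  # constraint must hold row-wise after repair
  ok <- purrr::map_lgl(seq_len(n), function(i)
    !inherits(try(geometry_from_row(shape, out[i, ]), silent = TRUE), "try-error"))
  if (!all(ok)) stop("internal error: ", sum(!ok), " invalid designs after repair",
                     call. = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "shape") <- shape
  out
}

# Re-pair the r_big column against r_middle so every row satisfies
# r_big > r_middle, permuting realized values (which leaves every 1-D
# stratified projection untouched). A random greedy matching assigns, in
# decreasing order of r_middle, a uniformly chosen still-unused r_big value
# from those exceeding it; with the catalogue ranges a feasible matching
# always exists (pairing the sorted columns satisfies the constraint with
# margin), so a few random restarts suffice, with the sorted pairing as the
# deterministic last resort for any stuck tail.
.repair_conical <- function(u, ranges, n) {
  lo <- stats::setNames(ranges$low, ranges$parameter)
  hi <- stats::setNames(ranges$high, ranges$parameter)
  rb <- lo[["r_big_mm"]] + (hi[["r_big_mm"]] - lo[["r_big_mm"]]) * u[, "r_big_mm"]
  rm <- lo[["r_middle_mm"]] +
    (hi[["r_middle_mm"]] - lo[["r_middle_mm"]]) * u[, "r_middle_mm"]
  if (all(rb > rm)) return(u)
  ord <- order(rm, decreasing = TRUE)
  for (attempt in seq_len(200)) {
    pool <- rb  # values still unassigned
    used <- rep(FALSE, n)
    assign <- rep(NA_integer_, n)  # row -> index into rb
    ok <- TRUE
    for (row in ord) {
      eligible <- which(!used & rb > rm[row])
      if (!length(eligible)) { ok <- FALSE; break }
      pick <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      assign[row] <- pick
      used[pick] <- TRUE
    }
    if (ok) {
      u[, "r_big_mm"] <- u[assign, "r_big_mm"]
      return(u)
    }
  }
  # deterministic fallback: assortative pairing of the sorted columns
  assign <- integer(n)
  assign[ord] <- order(rb, decreasing = TRUE)
  u[, "r_big_mm"] <- u[assign, "r_big_mm"]
  rb2 <- lo[["r_big_mm"]] + (hi[["r_big_mm"]] - lo[["r_big_mm"]]) * u[, "r_big_mm"]
  if (!all(rb2 > rm))
    stop("constraint repair failed: no feasible r_big pairing", call. = FALSE)
  u
}

#' Run a nozzle-design campaign
#'
#' Evaluates every design of a [lhs_design()] table with the selected flow
#' solver under one material and drive condition, returning one flow-summary
#' row per design. Solver failures are captured, reported via the
#' `converged`/`error` columns and counted; more than 5% failures aborts the
#' campaign.
#'
#' @param designs design tibble from [lhs_design()] (mm columns).
#' @param mat a [material()].
#' @param drive a drive condition; defaults to the material's catalogue
#'   printing pressure.
#' @param solver `"reduced"` (default; seconds for 200 designs) or `"fvm"`.
#' @param ... further arguments passed to [solve_nozzle()].
#' @return a tibble: design columns + response columns `mss_kpa`,
#'   `flow_ul_s`, `v_exit_m_s`, `nu_exit_m2_s`, `delta_p_kpa`, `solver`, `ok`.
#' @export
run_campaign <- function(designs, mat,
                         drive = pressure_drive(mat$pressure_kpa),
                         solver = c("reduced", "fvm"), ...) {
  solver <- match.arg(solver)
  shape <- attr(designs, "shape")
  if (is.null(shape)) shape <- if ("r_middle_mm" %in% names(designs)) "conical" else "blunted"
  res <- purrr::map(seq_len(nrow(designs)), function(i) {
    row <- designs[i, ]
    out <- tryCatch({
      fs <- solve_nozzle(geometry_from_row(shape, row), mat, drive,
                         solver = solver, ...)
      tibble::tibble(mss_kpa = fs$mss_kpa, flow_ul_s = fs$flow_ul_s,
                     v_exit_m_s = fs$v_exit_m_s, nu_exit_m2_s = fs$nu_exit_m2_s,
                     delta_p_kpa = fs$delta_p_kpa, ok = TRUE, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(mss_kpa = NA_real_, flow_ul_s = NA_real_,
                     v_exit_m_s = NA_real_, nu_exit_m2_s = NA_real_,
                     delta_p_kpa = NA_real_, ok = FALSE, error = conditionMessage(e))
    })
    dplyr::bind_cols(row, out)
  })
  out <- dplyr::bind_rows(res)
  n_fail <- sum(!out$ok)
  if (n_fail > 0)
    warning(n_fail, " of ", nrow(out), " designs failed", call. = FALSE)
  if (n_fail > 0.05 * nrow(out))
    stop("campaign aborted: ", n_fail, "/", nrow(out), " solver failures (> 5%)",
         call. = FALSE)
  out$solver <- solver
  attr(out, "shape") <- shape
  attr(out, "seed") <- attr(designs, "seed")
  class(out) <- c("campaign_result", class(out))
  out
}

#' Distribution summary of campaign responses
#'
#' @param resp a [run_campaign()] result.
#' @param vars response columns to summarize.
#' @return a tibble with min/quartiles/median/max per response.
#' @export
summarize_campaign <- function(resp,
                               vars = c("mss_kpa", "flow_ul_s", "nu_exit_m2_s")) {
  if (nrow(resp) == 0) stop("empty campaign", call. = FALSE)
  long <- tidyr::pivot_longer(dplyr::filter(resp, .data$ok),
                              dplyr::all_of(vars),
                              names_to = "response", values_to = "value")
  dplyr::summarize(
    dplyr::group_by(long, .data$response),
    n = dplyr::n(),
    min = min(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    median = stats::median(.data$value),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    max = max(.data$value),
    .groups = "drop"
  )
}

#' Shear-thinning sweep of maximum shear stress
#'
#' Maximum shear stress as a function of one swept radius (`r_small` or, for
#' conical nozzles, `r_middle`) for a set of power-law indices, all other
#' geometry parameters held fixed. Reproduces the qualitative interplay
#' between shear-thinning strength and nozzle shape: at constant pressure the
#' blunted MSS grows with the exit radius, while the conical response to the
#' exit radius changes character between strongly shear-thinning and nearly
#' Newtonian inks.
#'
#' @param shape `"blunted"` or `"conical"`.
#' @param sweep `"r_small"` or `"r_middle"` (conical only).
#' @param values swept radii in mm.
#' @param n_values power-law indices in (0, 1].
#' @param k consistency coefficient (Pa s^n) shared by all indices.
#' @param drive drive condition (constant pressure by default).
#' @param rho density (kg/m^3).
#' @param r_small,r_middle,r_big,l_lower,l_upper fixed geometry (mm); the
#'   swept one is ignored. Defaults: `r_middle = 2.0` for the `r_small` sweep
#'   and `r_small = 0.2` for the `r_middle` sweep.
#' @param solver flow solver passed to [run_campaign()].
#' @param ... passed to [solve_nozzle()].
#' @return a tibble with `n`, the swept value and the response columns.
#' @export
shear_thinning_sweep <- function(shape = c("blunted", "conical"),
                                 sweep = c("r_small", "r_middle"),
                                 values = seq(0.05, 0.42, length.out = 8),
                                 n_values = c(0.1, 0.25, 0.5, 0.75),
                                 k = 55.7, drive = pressure_drive(340),
                                 rho = 1000,
                                 r_small = 0.2, r_middle = 2.0, r_big = 3.5,
                                 l_lower = 6, l_upper = 4,
                                 solver = "reduced", ...) {
  shape <- match.arg(shape)
  sweep <- match.arg(sweep)
  if (sweep == "r_middle" && shape != "conical")
    stop("r_middle sweep requires the conical shape", call. = FALSE)
  if (any(n_values <= 0 | n_values > 1))
    stop("power-law indices must lie in (0, 1]", call. = FALSE)
  grid <- tidyr::expand_grid(n = n_values, value = values)
  res <- purrr::pmap(grid, function(n, value) {
    rs <- if (sweep == "r_small") value else r_small
    rm <- if (sweep == "r_middle") value else r_middle
    geom <- if (shape == "blunted") blunted_nozzle(rs, r_big, l_lower, l_upper)
            else conical_nozzle(rs, rm, r_big, l_lower, l_upper)
    mat <- material(sprintf("sweep n=%g", n), rho = rho, k = k, n = n)
    fs <- solve_nozzle(geom, mat, drive, solver = solver, ...)
    tibble::tibble(n = n, !!paste0(sweep, "_mm") := value,
                   mss_kpa = fs$mss_kpa, flow_ul_s = fs$flow_ul_s,
                   delta_p_kpa = fs$delta_p_kpa)
  })
  dplyr::bind_rows(res)
}
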