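#' Literature compilation of shear-stress / cell-viability studies
#'
#' A packaged compilation of published extrusion-bioprinting experiments that
#' report cell viability together with the print settings (bioink power-law
#' parameters, printing pressure and/or flow-rate range, blunted-nozzle
#' dimensions). The fixture mirrors the published table digit for digit; this
#' loader parses the printed ranges into numeric `lo`/`hi` columns and flags
#' rows whose geometry or drive information is too incomplete to simulate
#' (marked with `*` in the source key).
#'
#' The nozzle size column is printed as "Nozzle diameter (Rs, mm)" — a
#' self-contradictory header. By default it is interpreted as a diameter
#' (exit radius = value/2), the reading under which the compilation's own
#' fully developed wall-stress values are reproduced; set
#' `rs_is_diameter = FALSE` for the radius reading.
#'
#' @param rs_is_diameter interpret the printed nozzle size as a diameter
#'   (default) rather than a radius.
#' @return a tibble of viability records with parsed numeric columns
#'   (`*_lo`/`*_hi`), the derived exit radius `r_small_mm`, and a
#'   `simulatable` flag.
#' @export
builtin_studies <- function(rs_is_diameter = TRUE) {
  path <- system.file("extdata", "viability_studies.csv", package = "nozzleflow",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  parse_range <- function(s) {
    s <- trimws(s)
    out <- matrix(NA_real_, length(s), 2)
    has <- nzchar(s)
    parts <- strsplit(s[has], "-", fixed = TRUE)
    out[has, ] <- t(vapply(parts, function(p) {
      v <- as.numeric(p)
      if (length(v) == 1) c(v, v) else v[1:2]
    }, numeric(2)))
    out
  }
  pr <- parse_range(raw$pressure_kpa)
  fl <- parse_range(raw$flow_ul_s)
  rs <- parse_range(raw$nozzle_diameter_rs_mm)
  mss <- parse_range(raw$mss_kpa)
  vi <- parse_range(raw$viability_pct)
  div <- if (rs_is_diameter) 2 else 1
  out <- tibble::tibble(
    study = paste0("S", sprintf("%02d", seq_len(nrow(raw))), "_",
                   sub("\\*$", "", raw$source)),
    material = raw$material,
    k = as.numeric(raw$k),
    n = as.numeric(raw$n),
    pressure_lo_kpa = pr[, 1], pressure_hi_kpa = pr[, 2],
    rs_col_lo_mm = rs[, 1], rs_col_hi_mm = rs[, 2],
    r_small_lo_mm = rs[, 1] / div, r_small_hi_mm = rs[, 2] / div,
    l_lower_mm = suppressWarnings(as.numeric(raw$l_lower_mm)),
    flow_lo_uls = fl[, 1], flow_hi_uls = fl[, 2],
    mss_lo_kpa = mss[, 1], mss_hi_kpa = mss[, 2],
    viability_lo_pct = vi[, 1], viability_hi_pct = vi[, 2],
    cell = raw$cell,
    source = raw$source,
    incomplete = grepl("\\*$", raw$source)
  )
  if (any(stats::na.omit(c(out$viability_lo_pct, out$viability_hi_pct)) < 0) ||
      any(stats::na.omit(c(out$viability_lo_pct, out$viability_hi_pct)) > 100))
    stop("viability outside [0, 100] in fixture", call. = FALSE)
  has_drive <- (!is.na(out$pressure_lo_kpa)) | (!is.na(out$flow_lo_uls))
  out$simulatable <- !out$incomplete & has_drive &
    !is.na(out$l_lower_mm) & !is.na(out$k) & !is.na(out$n)
  out
}

#' Recompute the maximum shear stress for each literature print condition
#'
#' For every simulatable record the low and high endpoint of the driving
#' variable (the pressure range when one is given, otherwise the flow-rate
#' range) is solved through a blunted nozzle with the record's exit radius and
#' lower length; the entrance radius and upper length missing from most
#' reports are filled from a catalogue default (`fill`). A zero-pressure
#' endpoint is the unsheared 2D control and is assigned zero stress without a
#' solve. The reported viability range is paired monotonically: the low-drive
#' endpoint carries the high viability.
#'
#' @param records tibble from [builtin_studies()].
#' @param solver `"reduced"` (default) or `"fvm"`.
#' @param fill default geometry for missing parameters (mm).
#' @param rho assumed bioink density (kg/m^3).
#' @param ... passed to [solve_nozzle()].
#' @return a tibble of study points: `study`, `endpoint`, `drive_var`,
#'   `drive_value`, `mss_kpa` (computed), `mss_reported_kpa`,
#'   `viability_pct`, `cell`.
#' @export
simulate_records <- function(records, solver = "reduced",
                             fill = list(r_big_mm = 3.5, l_upper_mm = 4.0),
                             rho = 1000, ...) {
  skipped <- records$study[!records$simulatable]
  if (length(skipped))
    message("skipping non-simulatable records: ", paste(skipped, collapse = ", "))
  recs <- dplyr::filter(records, .data$simulatable)
  pts <- purrr::map(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    mat <- material(r$material, rho = rho, k = r$k, n = r$n)
    use_pressure <- !is.na(r$pressure_lo_kpa) &&
      (r$pressure_hi_kpa > r$pressure_lo_kpa || is.na(r$flow_lo_uls))
    ends <- tibble::tibble(
      endpoint = c("low", "high"),
      drive_var = if (use_pressure) "pressure_kpa" else "flow_ul_s",
      drive_value = if (use_pressure) c(r$pressure_lo_kpa, r$pressure_hi_kpa)
                    else c(r$flow_lo_uls, r$flow_hi_uls),
      r_small_mm = c(r$r_small_lo_mm, r$r_small_hi_mm),
      mss_reported_kpa = c(r$mss_lo_kpa, r$mss_hi_kpa),
      viability_pct = c(r$viability_hi_pct, r$viability_lo_pct)
    )
    if (ends$drive_value[1] == ends$drive_value[2] &&
        ends$r_small_mm[1] == ends$r_small_mm[2])
      ends <- ends[1, ]
    ends$mss_kpa <- purrr::map2_dbl(ends$drive_value, ends$r_small_mm,
      function(v, rs_mm) {
        if (v == 0) return(0)  # 2D control
        geom <- blunted_nozzle(rs_mm, fill$r_big_mm, r$l_lower_mm,
                               fill$l_upper_mm)
        drive <- if (use_pressure) pressure_drive(v) else flow_drive(v)
        solve_nozzle(geom, mat, drive, solver = solver, ...)$mss_kpa
      })
    ends$study <- r$study
    ends$cell <- r$cell
    ends
  })
  out <- dplyr::bind_rows(pts)
  dplyr::select(out, "study", "cell", "endpoint", "drive_var", "drive_value",
                "r_small_mm", "mss_kpa", "mss_reported_kpa", "viability_pct")
}

#' Association between computed shear stress and reported viability
#'
#' Per study: Spearman rank correlation between the computed maximum shear
#' stress and the reported viability where at least `min_points` points are
#' available, otherwise a trend classified from the endpoints. A pooled
#' Spearman correlation is also computed over stem-cell studies (cell label
#' containing `"hMSC"`, `"ESC"` or `"stem"`), the group for which the adverse
#' effect of shear is most consistently reported.
#'
#' @param points tibble from [simulate_records()].
#' @param min_points minimum points per study for a correlation (default 3).
#' @param flat_threshold absolute viability change (percentage points) under
#'   which a two-point study is classified `"flat"`.
#' @return a list with `per_study` (study, n, spearman, trend) and `pooled`
#'   (group-level Spearman for all points and for stem-cell points).
#' @export
viability_association <- function(points, min_points = 3, flat_threshold = 5) {
  per_study <- dplyr::group_modify(
    dplyr::group_by(points, .data$study, .data$cell),
    function(d, key) {
      d <- d[is.finite(d$mss_kpa) & is.finite(d$viability_pct), ]
      n <- nrow(d)
      rho <- if (n >= min_points)
        suppressWarnings(stats::cor(d$mss_kpa, d$viability_pct,
                                    method = "spearman")) else NA_real_
      trend <- if (n < 2) NA_character_ else {
        dv <- d$viability_pct[which.max(d$mss_kpa)] -
          d$viability_pct[which.min(d$mss_kpa)]
        if (abs(dv) <= flat_threshold) "flat"
        else if (dv < 0) "negative" else "positive"
      }
      tibble::tibble(n = n, spearman = rho, trend = trend)
    })
  per_study <- dplyr::ungroup(per_study)
  pool_rho <- function(d) {
    d <- d[is.finite(d$mss_kpa) & is.finite(d$viability_pct), ]
    if (nrow(d) < 3) return(NA_real_)
    suppressWarnings(stats::cor(d$mss_kpa, d$viability_pct, method = "spearman"))
  }
  stem <- grepl("hMSC|ESC|stem", points$cell)
  pooled <- tibble::tibble(
    group = c("all", "stem_cells"),
    n = c(nrow(points), sum(stem)),
    spearman = c(pool_rho(points), pool_rho(points[stem, ]))
  )
  list(per_study = per_study, pooled = pooled)
}

#' Shear stress versus nozzle diameter at constant flow rate
#'
#' The flow-driven analogue of the printed-pressure campaigns: the maximum
#' shear stress through blunted nozzles of increasing exit diameter at a
#' fixed volumetric flow rate. MSS is strictly decreasing in the diameter
#' (wider exits shear less at equal throughput), the trend the flow-driven
#' viability experiments confirm.
#'
#' @param mat a [material()].
#' @param flow_uls constant flow rate (µL/s).
#' @param diameters_mm exit diameters to test (mm); radii must stay within
#'   the catalogue range.
#' @param l_lower_mm,r_big_mm,l_upper_mm fixed geometry (mm).
#' @param solver flow solver.
#' @param ... passed to [solve_nozzle()].
#' @return a tibble with `diameter_mm`, `r_small_mm`, `mss_kpa`,
#'   `delta_p_kpa`.
#' @export
constant_flow_diameter_sweep <- function(mat, flow_uls,
                                         diameters_mm = c(0.2, 0.4, 0.6, 0.84),
                                         l_lower_mm = 11, r_big_mm = 3.5,
                                         l_upper_mm = 4, solver = "reduced",
                                         ...) {
  rs <- diameters_mm / 2
  if (any(rs < 0.05 - 1e-9 | rs > 0.42 + 1e-9))
    stop("exit radii outside the catalogue range 0.05-0.42 mm", call. = FALSE)
  res <- purrr::map(rs, function(r) {
    fs <- solve_nozzle(blunted_nozzle(r, r_big_mm, l_lower_mm, l_upper_mm),
                       mat, flow_drive(flow_uls), solver = solver, ...)
    tibble::tibble(r_small_mm = r, mss_kpa = fs$mss_kpa,
                   delta_p_kpa = fs$delta_p_kpa)
  })
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, diameter_mm = 2 * .data$r_small_mm, .before = 1)
}
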