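#' Tidy and glance methods for the Gaussian-process surrogate
#'
#' `tidy()` returns one row per input with its length scale and sensitivity
#' ordering hint (shorter scaled length scale = more active input);
#' `glance()` returns the one-row model summary.
#'
#' @param x a [fit_gp()] surrogate.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gp_surrogate <- function(x, ...) {
  if (isTRUE(x$constant))
    return(tibble::tibble(parameter = x$parameters, lengthscale = NA_real_,
                          relevance = 0))
  tibble::tibble(
    parameter = x$parameters,
    lengthscale = as.numeric(x$lengthscales),
    relevance = 1 / as.numeric(x$lengthscales)^2
  )
}

#' @rdname tidy.gp_surrogate
#' @export
glance.gp_surrogate <- function(x, ...) {
  if (isTRUE(x$constant))
    return(tibble::tibble(n = nrow(x$x), constant = TRUE,
                          sigma_f = 0, sigma_n = 0, log_marginal = NA_real_))
  tibble::tibble(n = nrow(x$x), constant = FALSE, sigma_f = x$sigma_f,
                 sigma_n = x$sigma_n, log_marginal = x$log_marginal)
}

#' @export
tidy.sensitivity_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"boot")
}

# re-export the broom generics without depending on broom
#' Turn an object into a tidy tibble
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#' @param x object to summarize.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot methods for campaign, sensitivity, main-effect, sweep and viability
#' results
#'
#' `autoplot()` renders each result type the way the screening study is
#' usually presented: response distributions per campaign (box + violin),
#' centered main-effect curves with 90% bands, sensitivity box plots from the
#' bootstrap distribution, shear-thinning sweep trends, and the
#' stress-viability scatter on a log stress axis.
#'
#' @param object a result object from this package.
#' @param var response column for campaign plots.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot-nozzleflow
NULL

#' @rdname autoplot-nozzleflow
#' @importFrom ggplot2 autoplot
#' @export
autoplot.campaign_result <- function(object, var = "mss_kpa", ...) {
  lab <- c(mss_kpa = "maximum shear stress (kPa)",
           flow_ul_s = "flow rate (µL/s)",
           nu_exit_m2_s = "outlet kinematic viscosity (m²/s)")[var]
  ggplot2::ggplot(dplyr::filter(object, .data$ok),
                  ggplot2::aes(x = factor(1), y = .data[[var]])) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = lab %||% var) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname autoplot-nozzleflow
#' @export
autoplot.main_effect <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_scaled, .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci90_low,
                                      ymax = .data$ci90_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "scaled parameter (-1 = low, +1 = high)",
                  y = "centred scaled response") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nozzleflow
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  boot <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object), "parameter", "boot"), "boot")
  long <- tidyr::pivot_longer(boot, c("s_first", "s_total"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = NULL, y = "Sobol index") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nozzleflow
#' @export
plot_sweep <- function(object, ...) {
  xvar <- intersect(c("r_small_mm", "r_middle_mm"), names(object))[1]
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$mss_kpa,
                                       colour = factor(.data$n))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = paste(sub("_mm", "", xvar), "(mm)"),
                  y = "maximum shear stress (kPa)", colour = "n") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nozzleflow
#' @export
plot_viability <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(pmax(.data$mss_kpa, 0.01),
                                       .data$viability_pct,
                                       colour = .data$study,
                                       shape = .data$cell)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$study), linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "computed maximum shear stress (kPa, log scale)",
                  y = "reported cell viability (%)") +
    ggplot2::guides(shape = "none") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nozzleflow
#' @export
plot_wall_shear <- function(object, ...) {
  wp <- wall_profile(object)
  ggplot2::ggplot(wp, ggplot2::aes(.data$z_mm, .data$tau_w_kpa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (mm)", y = "wall shear stress (kPa)") +
    ggplot2::theme_minimal()
}
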