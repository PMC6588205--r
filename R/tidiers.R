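# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flow solution
#'
#' One row per segment: flow, velocity, viscosity and wall shear stress,
#' with the endpoint pressures joined on.
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy flow_solution
#' @export
tidy.flow_solution <- function(x, ...) {
  dplyr::mutate(x$segments,
                p_from_mmHg = x$nodes$pressure_mmHg[.data$from],
                p_to_mmHg = x$nodes$pressure_mmHg[.data$to])
}

#' Summarise a flow solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return One-row tibble: mean/sd pressure (mmHg), mean/sd |flow|
#'   (nl/min), mean/sd |velocity| (mm/s), mean/sd wall shear stress
#'   (dyn/cm2), and the worst interior mass-balance residual relative to
#'   the mean absolute flow.
#' @method glance flow_solution
#' @export
glance.flow_solution <- function(x, ...) {
  seg <- x$segments
  inflow <- rowsum(c(-seg$flow_nl_min, seg$flow_nl_min), c(seg$from, seg$to))
  node_ids <- as.integer(rownames(inflow))
  interior <- !(node_ids %in% x$nodes$id[x$nodes$is_boundary])
  mean_q <- mean(abs(seg$flow_nl_min))
  tibble::tibble(
    mean_pressure_mmHg = mean(x$nodes$pressure_mmHg),
    sd_pressure_mmHg = stats::sd(x$nodes$pressure_mmHg),
    mean_abs_flow_nl_min = mean_q,
    sd_abs_flow_nl_min = stats::sd(abs(seg$flow_nl_min)),
    mean_velocity_mm_s = mean(abs(seg$velocity_um_s)) / 1e3,
    mean_wss_dyn_cm2 = mean(seg$wss_dyn_cm2),
    sd_wss_dyn_cm2 = stats::sd(seg$wss_dyn_cm2),
    max_interior_imbalance_rel =
      if (any(interior) && mean_q > 0) max(abs(inflow[interior])) / mean_q else 0,
    estimated = isTRUE(x$estimated)
  )
}

#' Tidy a coupling result (convergence history)
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @return The iteration history tibble.
#' @method tidy coupling_result
#' @export
tidy.coupling_result <- function(x, ...) x$history

#' Summarise a coupling result
#' @param x A `coupling_result`.
#' @param ... Unused.
#' @return One-row tibble: iterations, convergence flag, final update
#'   sizes, and source/sink counts.
#' @method glance coupling_result
#' @export
glance.coupling_result <- function(x, ...) {
  q <- x$sources$q_cm3_s
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    final_max_dq_ul_min = utils::tail(x$history$max_dq_ul_min, 1),
    final_mean_dp_mmHg = utils::tail(x$history$mean_dp_mmHg, 1),
    n_sources = sum(q > 0), n_sinks = sum(q < 0)
  )
}

#' Tidy a baseline run
#' @param x A `baseline_run`.
#' @param ... Unused.
#' @return The radial-profile tibble (IFP and IFV per bin).
#' @method tidy baseline_run
#' @export
tidy.baseline_run <- function(x, ...) x$profiles

#' Summarise a baseline run
#' @param x A `baseline_run`.
#' @param ... Unused.
#' @return One-row tibble joining flow, coupling and perfusion summaries.
#' @method glance baseline_run
#' @export
glance.baseline_run <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$flow),
    glance(x$coupling),
    x$perfusion,
    tibble::tibble(mean_probe_ifp_mmHg = mean(x$probe_ifp),
                   mean_probe_ifv_um_s = mean(x$probe_ifv))
  )
}

#' Plot a radial profile
#'
#' Line plus standard-deviation ribbon against normalised tumour radius.
#'
#' @param object A `radial_profile` (or the `profiles` tibble of a run,
#'   which facets by quantity).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalised radius", y = "value")
  if ("quantity" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y")
  }
  p
}

#' Plot flow-solution distributions
#'
#' Histograms of nodal pressure, |segment flow| and wall shear stress.
#'
#' @param object A `flow_solution`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_solution
#' @export
autoplot.flow_solution <- function(object, bins = 30, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(quantity = "pressure (mmHg)", value = object$nodes$pressure_mmHg),
    tibble::tibble(quantity = "|flow| (nl/min)", value = abs(object$segments$flow_nl_min)),
    tibble::tibble(quantity = "wall shear stress (dyn/cm2)", value = object$segments$wss_dyn_cm2)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free") +
    ggplot2::labs(x = NULL, y = "count")
}

#' Plot a rasterised planar map
#'
#' @param map Output of [rasterize_field()].
#' @param label Fill legend label.
#' @return A ggplot tile map.
#' @export
plot_field_map <- function(map, label = "value") {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$px, y = .data$py, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = label)
}
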