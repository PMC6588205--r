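#' Starling update of the vascular pressures at sources
#'
#' One step of the vascular/interstitial coupling: the vascular pressure at
#' each source is lowered by the pressure equivalent of the fluid it loses
#' across the wall, `p_b - K_i J_v,i` with wall resistance
#' `K_i = 1/(L_p,i S_i)` (oncotic term held out of the update, as the
#' oncotic gradient is fixed). Sources with `L_p = 0` or zero flux are
#' unchanged.
#'
#' @param sources A `source_set` with solved strengths.
#' @param params An [interstitial_params()].
#' @param Jv Optional precomputed transvascular flux tibble from
#'   [transvascular_flux()].
#' @return The `source_set` with updated `p_b_mmHg`.
#' @export
update_vascular_pressures <- function(sources, params, Jv = NULL) {
  if (is.null(Jv)) Jv <- transvascular_flux(interstitial_field(sources, params))
  ps <- resolve_source_params(sources, params)
  S_cm2 <- 2 * pi * (sources$rv_um * tf_units$um_to_cm) * (sources$l_um * tf_units$um_to_cm)
  K <- ifelse(ps$L_p > 0, 1 / (ps$L_p * S_cm2), 0)  # L_p = 0 sources carry no flux
  sources$p_b_mmHg <- sources$p_b_mmHg - K * Jv$J_v_cm3_s
  sources
}

#' Couple the vascular and interstitial compartments
#'
#' Fixed-point iteration: solve the source-strength system, update the
#' vascular pressures at the sources to account for the fluid each vessel
#' loses across its wall, and repeat until the largest change in any
#' source strength falls below `tolerance_ul_min` (default 1e-6 ul/min) or
#' `max_iter` is reached. The source geometry is fixed, so the system
#' matrix is assembled and inverted once. By default the update re-solves
#' the Poiseuille network with the transvascular fluxes applied as nodal
#' sinks (holding the boundary pressures of the supplied flow solution
#' fixed) and re-interpolates the vascular pressures at the sources;
#' because those losses are small relative to intravascular flow, the
#' iteration contracts within a few steps.
#'
#' @param network A `vascular_network`.
#' @param flow The baseline `flow_solution`.
#' @param sources A `source_set` from [distribute_sources()].
#' @param params An [interstitial_params()].
#' @param tolerance_ul_min Convergence tolerance on max |dq| (ul/min).
#' @param max_iter Iteration cap (default 50).
#' @param resolve_vascular Re-solve the vascular network each iteration
#'   with the transvascular fluxes applied as nodal sinks (default `TRUE`;
#'   the losses are small, so this converges in a few iterations). With
#'   `FALSE`, only the vascular pressures at the sources are updated by
#'   Starling's law; that literal update has a zero-filtration fixed point
#'   and is retained for sensitivity studies only.
#' @param conductance Network conductance (assembled with default
#'   haemodynamic parameters when missing and `resolve_vascular = TRUE`).
#' @return A list of class `coupling_result`: `field` (an
#'   `interstitial_field` with converged strengths), `sources`, `history`
#'   (tibble: iteration, max_dq_ul_min, mean_dp_mmHg), `converged`,
#'   `iterations`.
#' @export
couple <- function(network, flow, sources, params = interstitial_params(),
                   tolerance_ul_min = 1e-6, max_iter = 50L,
                   resolve_vascular = TRUE, conductance = NULL) {
  if (resolve_vascular && is.null(conductance)) {
    conductance <- assemble_conductance(network, haemo_params())
  }
  ps <- resolve_source_params(sources, params)
  active_any <- any(ps$L_p > 0)
  history <- tibble::tibble(iteration = integer(), max_dq_ul_min = numeric(),
                            mean_dp_mmHg = numeric())
  if (!active_any) {
    sources$q_cm3_s <- 0
    return(structure(list(field = interstitial_field(sources, params),
                          sources = sources,
                          history = tibble::tibble(iteration = 1L, max_dq_ul_min = 0,
                                                   mean_dp_mmHg = 0),
                          converged = TRUE, iterations = 1L),
                     class = "coupling_result"))
  }
  system <- assemble_source_system(sources, params)
  Ainv <- solve(system$A)
  q_prev <- rep(0, nrow(sources))
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    b <- sources$p_b_mmHg[system$active] - params$p_inf_mmHg -
      system$resolved$sigma[system$active] * (params$Pi_b_mmHg - params$Pi_v_mmHg)
    q <- rep(0, nrow(sources))
    q[system$active] <- drop(Ainv %*% b)
    sources$q_cm3_s <- q
    dq <- max(abs(q - q_prev)) * tf_units$cm3s_to_ul_min
    Jv <- transvascular_flux(interstitial_field(sources, params))
    p_old <- sources$p_b_mmHg
    if (resolve_vascular) {
      sources <- resolve_vascular_pressures(network, flow, sources, conductance, Jv)
    } else {
      sources <- update_vascular_pressures(sources, params, Jv)
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      iteration = it, max_dq_ul_min = dq,
      mean_dp_mmHg = mean(abs(sources$p_b_mmHg - p_old))
    ))
    q_prev <- q
    if (dq < tolerance_ul_min) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("coupling did not reach ", tolerance_ul_min, " ul/min in ", max_iter,
            " iterations (last max |dq| = ", signif(history$max_dq_ul_min[it], 3), ")")
  }
  structure(list(field = interstitial_field(sources, params), sources = sources,
                 history = history, converged = converged, iterations = it),
            class = "coupling_result")
}

# re-solve nodal pressures with transvascular losses as nodal sinks, fixing
# the boundary pressures of the reference flow solution; then re-interpolate
# vascular pressures at the sources
resolve_vascular_pressures <- function(network, flow, sources, conductance, Jv) {
  nn <- nrow(network$nodes)
  bn <- boundary_nodes(network)
  segs <- network$segments
  # deposit each source's wall loss on its segment endpoints by its position
  loss <- numeric(nn)
  n_sub <- tabulate(sources$segment, nbins = nrow(segs))
  tfrac <- stats::ave(seq_len(nrow(sources)), sources$segment, FUN = seq_along)
  tfrac <- (tfrac - 0.5) / n_sub[sources$segment]
  loss_from <- rowsum((1 - tfrac) * Jv$J_v_cm3_s, segs$from[sources$segment])
  loss_to <- rowsum(tfrac * Jv$J_v_cm3_s, segs$to[sources$segment])
  loss[as.integer(rownames(loss_from))] <- loss[as.integer(rownames(loss_from))] + loss_from
  loss[as.integer(rownames(loss_to))] <- loss[as.integer(rownames(loss_to))] + loss_to
  K <- conductance$K
  free <- setdiff(seq_len(nn), bn)
  p <- flow$nodes$pressure_mmHg
  rhs <- loss[free] - drop(as.matrix(K[free, bn, drop = FALSE] %*% p[bn]))
  p[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  tfrac_all <- tfrac
  sources$p_b_mmHg <- p[segs$from[sources$segment]] +
    tfrac_all * (p[segs$to[sources$segment]] - p[segs$from[sources$segment]])
  sources
}

#' @method print coupling_result
#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result> ", x$iterations, " iterations; ",
      if (x$converged) "converged" else "NOT converged",
      "; final max |dq| = ", signif(utils::tail(x$history$max_dq_ul_min, 1), 3),
      " ul/min\n", sep = "")
  invisible(x)
}
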