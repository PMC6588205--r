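#' Haemodynamic parameter set
#'
#' Parameters of the vascular compartment: discharge haematocrit, plasma
#' viscosity, and the targets/weights of the boundary-condition estimation
#' scheme. Target pressure and wall shear stress encode "typical network
#' haemodynamics" the estimator pulls the solution towards wherever boundary
#' data are unknown; they are tunable and exposed, never hard-coded.
#'
#' @param haematocrit Discharge haematocrit H, dimensionless in `[0, 1)`
#'   (default 0.45).
#' @param plasma_viscosity_cP Plasma viscosity in centipoise (default 1.05).
#' @param p_target_mmHg Target nodal pressure `p_0` (default 31 mmHg).
#' @param tau_target_dyn_cm2 Target wall shear stress magnitude `tau_0`
#'   (default 15 dyn/cm2).
#' @param k_p Weight of the pressure deviation term (default 0.1).
#' @param k_tau Weight of the shear deviation term; `NULL` (default)
#'   auto-scales it on the first estimation solve so both penalty terms are
#'   comparable.
#' @param direction_iter_cap Cap on shear-target direction fixed-point
#'   iterations (default 100).
#' @return A list of class `haemo_params`.
#' @export
haemo_params <- function(haematocrit = 0.45, plasma_viscosity_cP = 1.05,
                         p_target_mmHg = 31, tau_target_dyn_cm2 = 15,
                         k_p = 0.1, k_tau = NULL, direction_iter_cap = 100L) {
  stopifnot(haematocrit >= 0, haematocrit < 1, plasma_viscosity_cP > 0,
            k_p > 0, is.null(k_tau) || k_tau > 0)
  structure(list(haematocrit = haematocrit,
                 plasma_viscosity_cP = plasma_viscosity_cP,
                 p_target_mmHg = p_target_mmHg,
                 tau_target_dyn_cm2 = tau_target_dyn_cm2,
                 k_p = k_p, k_tau = k_tau,
                 direction_iter_cap = as.integer(direction_iter_cap)),
            class = "haemo_params")
}

#' Effective in vivo blood viscosity
#'
#' Empirical in vivo apparent-viscosity relation for blood flowing in a
#' microvessel, capturing the Fahraeus-Lindqvist diameter dependence and the
#' haematocrit dependence. The relative viscosity is
#' \deqn{\mu_{rel} = \left[1 + (\mu_{0.45} - 1)\,
#'   \frac{(1-H)^C - 1}{(1-0.45)^C - 1}\,
#'   \left(\frac{d}{d-1.1}\right)^2\right]\left(\frac{d}{d-1.1}\right)^2}
#' with \eqn{\mu_{0.45} = 6 e^{-0.085 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}}}
#' and shape exponent
#' \eqn{C = (0.8 + e^{-0.075 d})(-1 + 1/(1+10^{-11} d^{12})) +
#'   1/(1+10^{-11} d^{12})}, `d` in micron.
#'
#' @param d_um Vessel diameter(s), micron (> 1.1 um; the in vivo relation
#'   includes an endothelial layer term singular at 1.1 um).
#' @param haematocrit Discharge haematocrit in `[0, 1)`.
#' @param plasma_viscosity_cP Plasma viscosity, cP.
#' @return Effective viscosity in cP (plasma viscosity times the relative
#'   in vivo viscosity).
#' @export
effective_viscosity <- function(d_um, haematocrit = 0.45, plasma_viscosity_cP = 1.05) {
  if (any(d_um <= 0)) stop("vessel diameter must be > 0")
  if (any(d_um <= 1.1)) stop("in vivo viscosity law undefined for d <= 1.1 um")
  H <- haematocrit
  mu45 <- 6 * exp(-0.085 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  inv <- 1 / (1 + 1e-11 * d_um^12)
  C <- (0.8 + exp(-0.075 * d_um)) * (-1 + inv) + inv
  fl <- (d_um / (d_um - 1.1))^2
  hr <- if (H == 0) 0 else ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
  plasma_viscosity_cP * (1 + (mu45 - 1) * hr * fl) * fl
}

#' Assemble the network conductance system
#'
#' Builds the node-segment incidence matrix `L`, the signed segment
#' conductance matrix `M` with entries \eqn{\pm \pi d_j^4 / (128 \mu_j l_j)},
#' and the assembled nodal conductance `K = L M`. Effective viscosities come
#' from [effective_viscosity()]. All entries are in the internal
#' {cm, s, mmHg} system, so conductances are cm3/(s mmHg).
#'
#' @param network A `vascular_network`.
#' @param params A [haemo_params()] set.
#' @return A list of class `network_conductance` with sparse `L`, `M`, `K`,
#'   the per-segment conductance vector `g` (cm3/s/mmHg) and viscosities
#'   `mu_cP`.
#' @export
assemble_conductance <- function(network, params = haemo_params()) {
  segs <- network$segments
  nn <- nrow(network$nodes)
  ns <- nrow(segs)
  mu_cP <- effective_viscosity(segs$diameter, params$haematocrit,
                               params$plasma_viscosity_cP)
  d_cm <- segs$diameter * tf_units$um_to_cm
  l_cm <- segs$length * tf_units$um_to_cm
  mu <- mu_cP * tf_units$cp_to_mmhg_s
  g <- pi * d_cm^4 / (128 * mu * l_cm)
  L <- Matrix::sparseMatrix(
    i = c(segs$from, segs$to), j = c(seq_len(ns), seq_len(ns)),
    x = c(rep(-1, ns), rep(1, ns)), dims = c(nn, ns)
  )
  M <- Matrix::sparseMatrix(
    i = c(seq_len(ns), seq_len(ns)), j = c(segs$from, segs$to),
    x = c(g, -g), dims = c(ns, nn)
  )
  K <- L %*% M
  structure(list(L = L, M = M, K = K, g = g, mu_cP = mu_cP), class = "network_conductance")
}

new_flow_solution <- function(network, p_mmHg, conductance, estimated = FALSE,
                              lambda = NULL, extras = list()) {
  segs <- network$segments
  g <- conductance$g
  dp <- p_mmHg[segs$from] - p_mmHg[segs$to]
  Q_cm3s <- g * dp                      # positive start -> end
  imbalance <- drop(as.matrix(conductance$K %*% p_mmHg))  # = -Q0 (cm3/s)
  bn <- boundary_nodes(network)
  Q0 <- numeric(nrow(network$nodes))
  Q0[bn] <- -imbalance[bn]
  tau <- wall_shear_from(Q_cm3s, conductance$mu_cP, segs$diameter)
  v_cm_s <- Q_cm3s / (pi * (segs$diameter / 2 * tf_units$um_to_cm)^2)
  structure(c(list(
    nodes = tibble::tibble(
      id = network$nodes$id,
      pressure_mmHg = p_mmHg,
      boundary_flux_nl_min = Q0 * tf_units$cm3s_to_nl_min,
      is_boundary = network$nodes$id %in% bn
    ),
    segments = tibble::tibble(
      id = segs$id, from = segs$from, to = segs$to,
      flow_nl_min = Q_cm3s * tf_units$cm3s_to_nl_min,
      velocity_um_s = v_cm_s * tf_units$cm_s_to_um_s,
      viscosity_cP = conductance$mu_cP,
      wss_dyn_cm2 = tau
    ),
    estimated = estimated, lambda = lambda
  ), extras), class = "flow_solution")
}

#' @method print flow_solution
#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", nrow(x$nodes), " nodes; mean |Q| ",
      signif(mean(abs(x$segments$flow_nl_min)), 4), " nl/min; mean pressure ",
      signif(mean(x$nodes$pressure_mmHg), 4), " mmHg",
      if (isTRUE(x$estimated)) "; estimated BCs", "\n", sep = "")
  invisible(x)
}

wall_shear_from <- function(Q_cm3s, mu_cP, d_um) {
  d_cm <- d_um * tf_units$um_to_cm
  mu <- mu_cP * tf_units$cp_to_mmhg_s
  tau_mmHg <- 32 * mu * abs(Q_cm3s) / (pi * d_cm^3)
  tau_mmHg * tf_units$mmhg_to_dyn_cm2
}

#' Wall shear stress of a flow solution
#'
#' \eqn{\tau_j = 32 \mu_j |Q_j| / (\pi d_j^3)}, reported in dyn/cm2;
#' algebraically equal to \eqn{d_j |\Delta p_j| / (4 l_j)}.
#'
#' @param solution A `flow_solution`.
#' @param network The `vascular_network` it was solved on.
#' @return Numeric vector, one magnitude per segment (dyn/cm2).
#' @export
wall_shear_stress <- function(solution, network) {
  Q_cm3s <- solution$segments$flow_nl_min / tf_units$cm3s_to_nl_min
  wall_shear_from(Q_cm3s, solution$segments$viscosity_cP, network$segments$diameter)
}

#' Solve Poiseuille network flow with full boundary data
#'
#' Solves the nodal conservation system `K p = -Q0` with flux `Q0 = 0` at
#' interior nodes, prescribed pressures at `pressure_bcs` nodes and
#' prescribed boundary fluxes at `flux_bcs` nodes. Every boundary node must
#' carry exactly one condition and at least one pressure condition is needed
#' to fix the gauge (per connected component).
#'
#' @param network A `vascular_network`.
#' @param conductance From [assemble_conductance()].
#' @param pressure_bcs Named numeric vector: node id -> pressure (mmHg).
#' @param flux_bcs Named numeric vector: node id -> inflow (nl/min,
#'   positive into the network). Defaults to zero flux at no node.
#' @return A `flow_solution` with nodal pressures (mmHg), boundary fluxes
#'   (nl/min), per-segment flow (nl/min, positive start to end), velocities
#'   (um/s), viscosities (cP) and wall shear stresses (dyn/cm2).
#' @export
solve_poiseuille <- function(network, conductance, pressure_bcs, flux_bcs = numeric()) {
  nn <- nrow(network$nodes)
  bn <- boundary_nodes(network)
  p_nodes <- as.integer(names(pressure_bcs))
  q_nodes <- as.integer(names(flux_bcs))
  if (length(p_nodes) == 0L) stop("singular system: at least one pressure condition is required")
  uncovered <- setdiff(bn, c(p_nodes, q_nodes))
  if (length(uncovered)) {
    stop("boundary node(s) without a condition: ", paste(utils::head(uncovered, 5), collapse = ", "))
  }
  # components each need a pressure condition
  g <- igraph::graph_from_edgelist(cbind(network$segments$from, network$segments$to),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nn - igraph::vcount(g)))
  comp <- igraph::components(g)
  has_p <- tabulate(comp$membership[p_nodes], nbins = comp$no) > 0
  if (!all(has_p)) {
    stop("disconnected component(s) without a pressure condition: ",
         paste(which(!has_p), collapse = ", "))
  }
  K <- conductance$K
  rhs <- numeric(nn)
  rhs[q_nodes] <- -flux_bcs / tf_units$cm3s_to_nl_min  # K p = -Q0; Q0 > 0 = inflow
  free <- setdiff(seq_len(nn), p_nodes)
  p <- numeric(nn)
  p[p_nodes] <- pressure_bcs
  rhs_free <- rhs[free] - drop(as.matrix(K[free, p_nodes, drop = FALSE] %*% pressure_bcs))
  p[free] <- as.numeric(Matrix::solve(K[free, free], rhs_free))
  new_flow_solution(network, p, conductance)
}

# signed shear coefficient matrix: tau_signed = C p (internal units, mmHg ->
# mmHg of shear); row j has +-d_j/(4 l_j) at the segment endpoints
shear_coeff_matrix <- function(network) {
  segs <- network$segments
  coef <- segs$diameter / (4 * segs$length)  # dimensionless ratio; (cm/cm)
  Matrix::sparseMatrix(
    i = c(segs$id, segs$id), j = c(segs$from, segs$to),
    x = c(coef, -coef), dims = c(nrow(segs), nrow(network$nodes))
  )
}

#' Estimate network flow with incomplete boundary data
#'
#' Constrained-optimisation flow estimation: unknown boundary conditions are
#' resolved by minimising the weighted squared deviation of nodal pressures
#' and segment wall shear stresses from target values, subject to exact flux
#' conservation at interior and known-flux nodes. The stationarity system in
#' (pressures, Lagrange multipliers) is sparse, symmetric and solved
#' directly. Because the sign of the target shear must match the flow
#' direction, the solve is wrapped in a fixed-point loop over segment
#' direction signs (zero-flow segments keep their previous direction).
#'
#' @param network A `vascular_network`.
#' @param conductance From [assemble_conductance()].
#' @param pressure_bcs Named numeric vector: node id -> known pressure (mmHg).
#' @param flux_bcs Named numeric vector: node id -> known boundary inflow
#'   (nl/min); blind ends are zero entries here.
#' @param params A [haemo_params()] set supplying targets and weights.
#' @return A `flow_solution` with `estimated = TRUE` and extra fields
#'   `objective_trace` (first two penalty terms per direction iteration),
#'   `direction_iterations`, `direction_converged`.
#' @export
estimate_flow <- function(network, conductance, pressure_bcs, flux_bcs = numeric(),
                          params = haemo_params()) {
  nn <- nrow(network$nodes)
  segs <- network$segments
  bn <- boundary_nodes(network)
  p_nodes <- as.integer(names(pressure_bcs))
  q_nodes <- as.integer(names(flux_bcs))
  if (length(p_nodes) == 0L) stop("at least one known pressure condition is required")
  unknown_b <- setdiff(bn, c(p_nodes, q_nodes))
  constraint_nodes <- sort(c(interior_nodes(network), q_nodes))

  K <- conductance$K
  C <- shear_coeff_matrix(network)
  l_cm <- segs$length * tf_units$um_to_cm
  # w_k: half the summed length of segments incident to node k (cm)
  w <- 0.5 * (tabulate2(segs$from, l_cm, nn) + tabulate2(segs$to, l_cm, nn))
  tau0_mmHg <- params$tau_target_dyn_cm2 / tf_units$mmhg_to_dyn_cm2
  p0 <- rep(params$p_target_mmHg, nn)

  Q0_c <- numeric(length(constraint_nodes))
  known_flux_pos <- match(q_nodes, constraint_nodes)
  Q0_c[known_flux_pos] <- flux_bcs / tf_units$cm3s_to_nl_min

  free <- setdiff(seq_len(nn), p_nodes)
  p_fix <- as.numeric(pressure_bcs)

  # auto-scale k_tau so both penalty terms are comparable on the first solve
  k_p <- params$k_p
  k_tau <- params$k_tau

  # constraint rows are rescaled to O(1) conductance so the saddle system
  # stays well conditioned across wide diameter ranges (lambda rescaled back)
  g_scale <- stats::median(conductance$g)
  solve_saddle <- function(s, k_tau) {
    CtLC <- Matrix::crossprod(C, C * l_cm)  # C' diag(l) C
    H <- k_p * Matrix::Diagonal(nn, w) + k_tau * CtLC
    gvec <- k_p * w * p0 + k_tau * as.numeric(Matrix::crossprod(C, l_cm * (s * tau0_mmHg)))
    A <- K[constraint_nodes, , drop = FALSE] / g_scale
    lhs <- rbind(
      cbind(H[free, free, drop = FALSE], Matrix::t(A[, free, drop = FALSE])),
      cbind(A[, free, drop = FALSE],
            Matrix::Matrix(0, length(constraint_nodes), length(constraint_nodes), sparse = TRUE))
    )
    rhs <- c(
      gvec[free] - drop(as.matrix(H[free, p_nodes, drop = FALSE] %*% p_fix)),
      (-Q0_c - drop(as.matrix(K[constraint_nodes, p_nodes, drop = FALSE] %*% p_fix))) / g_scale
    )
    sol <- as.numeric(Matrix::solve(lhs, rhs))
    p <- numeric(nn)
    p[p_nodes] <- p_fix
    p[free] <- sol[seq_along(free)]
    lambda <- sol[-seq_along(free)] / g_scale
    list(p = p, lambda = lambda)
  }

  objective_terms <- function(p, s, k_tau) {
    tau_s <- as.numeric(C %*% p)
    c(p_term = 0.5 * k_p * sum(w * (p - p0)^2),
      tau_term = 0.5 * k_tau * sum(l_cm * (tau_s - s * tau0_mmHg)^2))
  }

  s <- rep(1, nrow(segs))
  if (is.null(k_tau)) {
    first <- solve_saddle(s, 1)
    terms <- objective_terms(first$p, s, 1)
    k_tau <- if (terms[["tau_term"]] > 0) k_p * max(terms[["p_term"]], 1e-12) / terms[["tau_term"]] else k_p
  }
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  sol <- NULL
  flips <- integer(nrow(segs))
  repeat {
    it <- it + 1L
    sol <- solve_saddle(s, k_tau)
    trace <- c(trace, sum(objective_terms(sol$p, s, k_tau)))
    q_sign <- sign(conductance$g * (sol$p[segs$from] - sol$p[segs$to]))
    s_new <- ifelse(q_sign == 0 | s == 0, s, q_sign)
    changed <- s_new != s
    flips <- flips + changed
    # segments that keep reversing have no stable preferred direction; zero
    # their shear target so the fixed point can settle
    s_new[flips >= 5L] <- 0
    if (!any(s_new != s)) { converged <- TRUE; break }
    if (it >= params$direction_iter_cap) break
    s <- s_new
  }
  if (!converged) {
    warning("direction fixed-point iteration hit the cap (", params$direction_iter_cap,
            "); returning last iterate")
  }
  new_flow_solution(network, sol$p, conductance, estimated = TRUE, lambda = sol$lambda,
                    extras = list(objective_trace = trace,
                                  direction_iterations = it,
                                  direction_converged = converged,
                                  k_tau_used = k_tau))
}
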