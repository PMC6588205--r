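# Shared fixtures, built once per test run and memoised. All stochastic
# fixtures are seeded, so the suite is deterministic.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small tumour-like network with hull, boundary conditions and an estimated
# flow solution -- the workhorse fixture for flow/interstitial/pipeline tests
fx_tumour <- function() {
  fx_memo("tumour", function() {
    net <- make_fixture(synthetic_spec("tumour_like",
                                       extent_um = c(2200, 2000, 2400), seed = 2))
    hull <- compute_hull(node_coords(net), 1L)
    hp <- haemo_params()
    cond <- assemble_conductance(net, hp)
    bcs <- assign_boundary_conditions(net, hull, boundary_policy(seed = 2))
    flow <- estimate_flow(net, cond, bcs$pressure_bcs, bcs$flux_bcs, hp)
    list(net = net, hull = hull, hp = hp, cond = cond, bcs = bcs, flow = flow)
  })
}

# coupled interstitial solution on the tumour fixture (Table-2-style params)
fx_coupled <- function() {
  fx_memo("coupled", function() {
    fx <- fx_tumour()
    ip <- interstitial_params()
    sources <- distribute_sources(fx$net, fx$flow, 80)
    cp <- couple(fx$net, fx$flow, sources, ip, conductance = fx$cond)
    probe <- tumourflow:::hull_probe_points(fx$hull, 600, seed = 5)
    list(ip = ip, sources = sources, cp = cp, probe = probe,
         ifp = evaluate_ifp(probe, cp$field))
  })
}

# 10x10x10 lattice with corner pressure conditions solved exactly
fx_lattice <- function() {
  fx_memo("lattice", function() {
    net <- make_fixture(synthetic_spec("lattice3d", k = 10L,
                                       branch_length_um = 100, diameter_mean_um = 10))
    hp <- haemo_params()
    cond <- assemble_conductance(net, hp)
    n <- nrow(net$nodes)
    bc <- stats::setNames(c(40, 20), c(1L, n))
    sol <- solve_poiseuille(net, cond, bc)
    list(net = net, hp = hp, cond = cond, bc = bc, sol = sol)
  })
}

# ten clustered regularized sources with solved strengths (oracle fixture)
fx_ten_sources <- function() {
  fx_memo("ten_sources", function() {
    set.seed(11)
    n <- 10L
    pos <- matrix(stats::runif(3 * n, -30, 30), ncol = 3)
    src <- tumourflow:::new_source_set(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      r0_um = rep(8, n), rv_um = rep(8, n), l_um = rep(20, n),
      segment = seq_len(n), p_b_mmHg = stats::runif(n, 20, 40)
    )
    ip <- interstitial_params()
    src <- solve_source_strengths(assemble_source_system(src, ip))
    list(src = src, ip = ip, field = interstitial_field(src, ip))
  })
}

# interior mass-balance residual of a flow solution, relative to mean |Q|
mass_balance_rel <- function(solution, network, exclude = integer()) {
  seg <- solution$segments
  inflow <- rep(0, nrow(network$nodes))
  agg <- rowsum(c(-seg$flow_nl_min, seg$flow_nl_min), c(seg$from, seg$to))
  inflow[as.integer(rownames(agg))] <- agg
  interior <- setdiff(seq_len(nrow(network$nodes)),
                      c(boundary_nodes(network), exclude))
  max(abs(inflow[interior])) / mean(abs(seg$flow_nl_min))
}
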