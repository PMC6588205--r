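# Stochastic boundary-condition assignment: vessels crossing the tumour
# surface connect to the peritumoural circulation and receive high/low
# pressures; a fraction of interior terminals are blind ends (zero flux);
# the rest are left unknown for the flow estimator.

#' Boundary assignment policy
#'
#' @param fraction Fraction of surface boundary nodes given a pressure
#'   condition (default 0.05).
#' @param p_high_mmHg,p_low_mmHg The two pressure extremes (mmHg).
#' @param blind_fraction Fraction of the remaining boundary nodes treated
#'   as blind ends with zero flux (default 0.33).
#' @param exclusion_fraction Principal diameters of the exclusion ellipsoid
#'   around an assigned extreme, as a fraction of the tissue bounding-box
#'   dimensions (default 0.05). Opposite extremes may not fall inside each
#'   other's ellipsoid (steep local gradients produce unphysiological
#'   flows).
#' @param seed Integer seed; all assignment randomness derives from it.
#' @return A list of class `boundary_policy`.
#' @export
boundary_policy <- function(fraction = 0.05, p_high_mmHg = 45, p_low_mmHg = 15,
                            blind_fraction = 0.33, exclusion_fraction = 0.05,
                            seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, blind_fraction >= 0, blind_fraction <= 1,
            exclusion_fraction >= 0, exclusion_fraction <= 1,
            p_high_mmHg > p_low_mmHg)
  structure(list(fraction = fraction, p_high_mmHg = p_high_mmHg,
                 p_low_mmHg = p_low_mmHg, blind_fraction = blind_fraction,
                 exclusion_fraction = exclusion_fraction, seed = as.integer(seed)),
            class = "boundary_policy")
}

#' Classify boundary nodes as surface or internal
#'
#' Boundary (degree-1) nodes within `depth_tolerance_um` of the hull surface
#' are "surface" nodes, assumed connected to peritumoural vessels; the rest
#' are internal terminals (angiogenic blind ends or imaging artefacts).
#' Depth is the minimum distance to the hull's face planes.
#'
#' @param network A `vascular_network`.
#' @param hull A `tumour_hull` enclosing the network.
#' @param depth_tolerance_um Surface depth tolerance (micron); default is
#'   twice the mean vessel diameter (scale-aware).
#' @return A list with integer node-id vectors `surface` and `internal`.
#' @export
classify_surface_nodes <- function(network, hull, depth_tolerance_um = NULL) {
  if (is.null(depth_tolerance_um)) {
    depth_tolerance_um <- 2 * mean(network$segments$diameter)
  }
  bn <- boundary_nodes(network)
  pts <- node_coords(network)[bn, , drop = FALSE]
  d <- rowSums(hull$face_normals * hull$vertices[hull$faces[, 1], , drop = FALSE])
  depth <- apply(sweep(-(pts %*% t(hull$face_normals)), 2L, d, "+"), 1L, min)
  surf <- depth <= depth_tolerance_um
  list(surface = bn[surf], internal = bn[!surf])
}

#' Assign surface pressure boundary conditions
#'
#' Shuffles the surface boundary nodes with the policy seed, takes the top
#' `floor(fraction * n)` (minimum 2, so both extremes can occur), and
#' assigns each the high or low extreme with equal probability. A
#' candidate extreme that would fall inside the exclusion ellipsoid of an
#' already-assigned opposite extreme is re-drawn; after
#' `100 * n_assign` failed redraws an error suggests lowering the fraction.
#'
#' @param surface_nodes Integer node ids (from [classify_surface_nodes()]).
#' @param network The `vascular_network`.
#' @param policy A [boundary_policy()].
#' @return Named numeric vector: node id -> pressure (mmHg).
#' @export
assign_surface_pressures <- function(surface_nodes, network, policy) {
  n <- length(surface_nodes)
  if (n < 1L) stop("no surface boundary nodes to assign")
  n_assign <- max(2L, floor(policy$fraction * n))
  n_assign <- min(n_assign, n)
  dims <- apply(node_coords(network), 2L, function(v) diff(range(v)))
  semi <- pmax(policy$exclusion_fraction * dims / 2, 1e-9)
  xyz <- node_coords(network)
  with_seed(policy$seed, {
    chosen <- sample(surface_nodes)[seq_len(n_assign)]
    values <- numeric(n_assign)
    assigned_pos <- xyz[chosen, , drop = FALSE]
    redraws <- 0L
    cap <- 100L * n_assign
    for (i in seq_len(n_assign)) {
      repeat {
        val <- sample(c(policy$p_high_mmHg, policy$p_low_mmHg), 1L)
        opp <- which(seq_len(n_assign) < i & values != val & values != 0)
        conflict <- FALSE
        if (length(opp)) {
          rel <- sweep(assigned_pos[opp, , drop = FALSE], 2L, assigned_pos[i, ], "-")
          conflict <- any(rowSums(sweep(rel, 2L, semi, "/")^2) <= 1)
        }
        if (!conflict) { values[i] <- val; break }
        redraws <- redraws + 1L
        if (redraws > cap) {
          stop("could not satisfy the exclusion region after ", redraws,
               " redraws; use a smaller assignment fraction or exclusion region")
        }
      }
    }
    stats::setNames(values, chosen)
  })
}

#' Assign blind ends among the remaining boundary nodes
#'
#' A seeded uniform selection of `floor(blind_fraction * n)` of the
#' remaining (unassigned) boundary nodes receives zero-flux conditions; the
#' rest stay unknown for the flow estimator.
#'
#' @param remaining_nodes Integer node ids.
#' @param policy A [boundary_policy()].
#' @return A list with `blind` (named zero vector: node -> flux nl/min) and
#'   `unknown` (integer ids).
#' @export
assign_blind_ends <- function(remaining_nodes, policy) {
  n <- length(remaining_nodes)
  n_blind <- floor(policy$blind_fraction * n)
  with_seed(policy$seed + 1L, {
    shuffled <- if (n > 0L) sample(remaining_nodes) else integer(0)
    blind <- shuffled[seq_len(n_blind)]
    list(blind = stats::setNames(rep(0, n_blind), blind),
         unknown = sort(setdiff(remaining_nodes, blind)))
  })
}

#' Full stochastic boundary assignment
#'
#' Convenience wrapper: classify surface nodes, assign surface pressures,
#' then blind ends among all remaining boundary nodes. Assigned, blind and
#' unknown sets partition the boundary nodes exactly.
#'
#' @param network A `vascular_network`.
#' @param hull A `tumour_hull`.
#' @param policy A [boundary_policy()].
#' @param depth_tolerance_um Passed to [classify_surface_nodes()].
#' @return A list: `pressure_bcs` (named mmHg), `flux_bcs` (named nl/min,
#'   zeros), `unknown`, `surface`, `internal`.
#' @export
assign_boundary_conditions <- function(network, hull, policy,
                                       depth_tolerance_um = NULL) {
  cls <- classify_surface_nodes(network, hull, depth_tolerance_um)
  pressure_bcs <- assign_surface_pressures(cls$surface, network, policy)
  remaining <- setdiff(boundary_nodes(network), as.integer(names(pressure_bcs)))
  be <- assign_blind_ends(remaining, policy)
  list(pressure_bcs = pressure_bcs, flux_bcs = be$blind, unknown = be$unknown,
       surface = cls$surface, internal = cls$internal)
}

#' Calibrate boundary pressures to a perfusion target
#'
#' Grid search over candidate (p_high, p_low) pairs and assignment seeds:
#' for each candidate, assign boundary conditions, estimate network flow,
#' and compute total tissue perfusion; the first configuration within
#' `tolerance` (relative) of the target is accepted. Every trial is logged.
#'
#' @param network A `vascular_network`.
#' @param hull A `tumour_hull` (subdivided if the interstitial component is
#'   requested).
#' @param target_perfusion Target perfusion, ml/min/100g.
#' @param tolerance Relative acceptance tolerance (default 0.2).
#' @param pressure_pairs List of `c(p_high, p_low)` candidates (mmHg);
#'   defaults cover glioma-like (30/20) and colorectal-xenograft-like
#'   (45/15) pairs.
#' @param seeds Integer vector of assignment seeds per pair.
#' @param params A [haemo_params()].
#' @param policy_template A [boundary_policy()] supplying the fractions.
#' @return A list: `policy` (accepted `boundary_policy`), `flow`
#'   (`flow_solution`), `bcs`, `perfusion` (`perfusion_result`), `log`
#'   (tibble of all trials).
#' @export
calibrate_to_perfusion <- function(network, hull, target_perfusion,
                                   tolerance = 0.2,
                                   pressure_pairs = list(c(30, 20), c(45, 15)),
                                   seeds = 1:3, params = haemo_params(),
                                   policy_template = boundary_policy()) {
  stopifnot(target_perfusion > 0)
  conductance <- assemble_conductance(network, params)
  log <- tibble::tibble(trial = integer(), p_high = numeric(), p_low = numeric(),
                        seed = integer(), perfusion = numeric())
  trial <- 0L
  for (pair in pressure_pairs) {
    for (s in seeds) {
      trial <- trial + 1L
      pol <- boundary_policy(fraction = policy_template$fraction,
                             p_high_mmHg = pair[1], p_low_mmHg = pair[2],
                             blind_fraction = policy_template$blind_fraction,
                             exclusion_fraction = policy_template$exclusion_fraction,
                             seed = s)
      bcs <- assign_boundary_conditions(network, hull, pol)
      flow <- estimate_flow(network, conductance, bcs$pressure_bcs, bcs$flux_bcs, params)
      perf <- total_perfusion(flow, hull, field = NULL, network = network)
      log <- dplyr::bind_rows(log, tibble::tibble(
        trial = trial, p_high = pair[1], p_low = pair[2], seed = s,
        perfusion = perf$perfusion_ml_min_100g
      ))
      if (abs(perf$perfusion_ml_min_100g - target_perfusion) <=
            tolerance * target_perfusion) {
        return(list(policy = pol, flow = flow, bcs = bcs, perfusion = perf, log = log))
      }
    }
  }
  closest <- log[which.min(abs(log$perfusion - target_perfusion)), ]
  stop("calibration search exhausted; closest achieved perfusion ",
       signif(closest$perfusion, 4), " ml/min/100g (target ", target_perfusion,
       ") at p_high=", closest$p_high, ", p_low=", closest$p_low,
       ", seed=", closest$seed)
}
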