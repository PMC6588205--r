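# End-to-end orchestration: a config describes the network (file or
# synthetic spec), the haemodynamic, boundary and interstitial parameter
# blocks, and the coupling controls; run_baseline() executes the full
# workflow deterministically from the global seed.

#' Build a run configuration
#'
#' All defaults are the package's baseline study conditions: Table-style
#' interstitial parameters, 5%/33% boundary fractions, 45/15 mmHg pressure
#' extremes, 50 um source spacing, 1e-6 ul/min coupling tolerance. Every
#' stochastic element (boundary assignment, probe sampling, synthetic
#' generation) derives from the global `seed`. Unknown keys in the override
#' list are errors, so misspelt sensitivity studies fail loudly.
#'
#' @param ... Named overrides of the default configuration (nested lists
#'   merged shallowly per block).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    network = list(path = NULL, dialect = "csv",
                   kind = "tumour_like", extent_um = c(2200, 2000, 2400),
                   diameter_mean_um = 8.9, diameter_sd_um = 2.8,
                   branch_length_um = 88.8, density_pct = 0.37, k = 3L),
    haemo = list(haematocrit = 0.45, plasma_viscosity_cP = 1.05,
                 p_target_mmHg = 31, tau_target_dyn_cm2 = 15,
                 k_p = 0.1, k_tau = NULL, direction_iter_cap = 100L),
    boundary = list(fraction = 0.05, p_high = 45, p_low = 15,
                    blind_fraction = 0.33, exclusion_fraction = 0.05,
                    perfusion_target = NULL, perfusion_tolerance = 0.2,
                    pressure_pairs = list(c(30, 20), c(45, 15)),
                    calibration_seeds = 1:3),
    interstitial = list(p_inf_mmHg = 0, kappa = 1.7e-7, L_p = 2.8e-7,
                        sigma = 0.82, Pi_b_mmHg = 20, Pi_v_mmHg = 15,
                        self_term = "drop"),
    delta_um = 50,
    coupling = list(tolerance_ul_min = 1e-6, max_iter = 50L,
                    resolve_vascular = TRUE),
    hull_subdivisions = 1L,
    probe_n = 800L,
    n_bins = 10L,
    seed = 1L,
    out_dir = NULL
  )
  overrides <- list(...)
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    if (is.list(defaults[[key]]) && is.list(overrides[[key]]) &&
          !is.null(names(defaults[[key]]))) {
      sub <- overrides[[key]]
      bad <- setdiff(names(sub), names(defaults[[key]]))
      if (length(bad)) stop("unknown config key: ", key, "$", bad[1])
      defaults[[key]][names(sub)] <- sub
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with top-level keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the baseline coupled workflow
#'
#' Executes: load/generate network, validate and clean, hull construction,
#' stochastic boundary assignment (with optional perfusion calibration),
#' flow estimation, source distribution, vascular/interstitial coupling,
#' then field evaluation, radial profiles, source/sink balance and total
#' perfusion. A manifest (config hash, seed, package version) makes runs
#' exactly repeatable.
#'
#' @param config A [run_config()].
#' @return A list of class `baseline_run` with the intermediate objects
#'   (`network`, `hull`, `bcs`, `flow`, `sources`, `coupling`, `field`),
#'   summaries (`profiles`, `source_sink`, `perfusion`, `statistics`) and
#'   `manifest`.
#' @export
run_baseline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  network <- stage("network", {
    if (!is.null(config$network$path)) {
      read_network(config$network$path, config$network$dialect)
    } else {
      nc <- config$network
      make_fixture(synthetic_spec(
        kind = nc$kind, extent_um = nc$extent_um,
        diameter_mean_um = nc$diameter_mean_um, diameter_sd_um = nc$diameter_sd_um,
        branch_length_um = nc$branch_length_um, density_pct = nc$density_pct,
        k = nc$k, seed = config$seed
      ))
    }
  })
  network <- stage("clean", validate_and_clean(network, policy = "keep_largest")$network)
  hull <- stage("hull", compute_hull(node_coords(network), config$hull_subdivisions))
  hparams <- stage("haemo", do.call(haemo_params, config$haemo))
  iparams <- stage("interstitial", do.call(interstitial_params, config$interstitial))
  conductance <- stage("conductance", assemble_conductance(network, hparams))
  bc_block <- config$boundary
  policy <- boundary_policy(fraction = bc_block$fraction,
                            p_high_mmHg = bc_block$p_high, p_low_mmHg = bc_block$p_low,
                            blind_fraction = bc_block$blind_fraction,
                            exclusion_fraction = bc_block$exclusion_fraction,
                            seed = config$seed)
  if (!is.null(bc_block$perfusion_target)) {
    cal <- stage("calibration", calibrate_to_perfusion(
      network, hull, bc_block$perfusion_target, bc_block$perfusion_tolerance,
      bc_block$pressure_pairs, bc_block$calibration_seeds, hparams, policy
    ))
    policy <- cal$policy
    bcs <- cal$bcs
    flow <- cal$flow
    calibration_log <- cal$log
  } else {
    bcs <- stage("boundary", assign_boundary_conditions(network, hull, policy))
    flow <- stage("estimate_flow",
                  estimate_flow(network, conductance, bcs$pressure_bcs, bcs$flux_bcs, hparams))
    calibration_log <- NULL
  }
  sources <- stage("sources", distribute_sources(network, flow, config$delta_um))
  coupling <- stage("couple", couple(
    network, flow, sources, iparams,
    tolerance_ul_min = config$coupling$tolerance_ul_min,
    max_iter = config$coupling$max_iter,
    resolve_vascular = config$coupling$resolve_vascular,
    conductance = conductance
  ))
  probe <- hull_probe_points(hull, config$probe_n, seed = config$seed + 101L)
  ifp <- evaluate_ifp(probe, coupling$field)
  ifv <- sqrt(rowSums(evaluate_ifv(probe, coupling$field)^2))
  profiles <- dplyr::bind_rows(
    dplyr::mutate(radial_profile(probe, ifp, hull, config$n_bins), quantity = "ifp_mmHg"),
    dplyr::mutate(radial_profile(probe, ifv, hull, config$n_bins), quantity = "ifv_um_s")
  )
  perfusion <- stage("perfusion",
                     total_perfusion(flow, hull, coupling$field, network))
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tumourflow")),
    r_version = R.version.string,
    timestamp = NA_character_  # deliberately unset: hashes must not drift
  )
  out <- structure(list(
    config = config, network = network, hull = hull, policy = policy, bcs = bcs,
    flow = flow, sources = coupling$sources, coupling = coupling,
    field = coupling$field, probe_points = probe,
    probe_ifp = ifp, probe_ifv = ifv,
    profiles = profiles,
    source_sink = source_sink_ratio_profile(coupling$field, hull, config$n_bins),
    perfusion = perfusion,
    statistics = network_statistics(network, hull$volume_cm3),
    calibration_log = calibration_log,
    manifest = manifest
  ), class = "baseline_run")
  if (!is.null(config$out_dir)) write_run_artefacts(out, config$out_dir)
  out
}

write_run_artefacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$flow$nodes, file.path(out_dir, "flow_nodes.csv"), row.names = FALSE)
  utils::write.csv(run$flow$segments, file.path(out_dir, "flow_segments.csv"), row.names = FALSE)
  utils::write.csv(run$sources, file.path(out_dir, "sources.csv"), row.names = FALSE)
  utils::write.csv(run$profiles, file.path(out_dir, "radial_profiles.csv"), row.names = FALSE)
  utils::write.csv(run$coupling$history, file.path(out_dir, "coupling_history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(run$perfusion), file.path(out_dir, "perfusion.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @method print baseline_run
#' @export
print.baseline_run <- function(x, ...) {
  cat("<baseline_run> seed ", x$config$seed, "; ", nrow(x$network$segments),
      " segments; perfusion ", signif(x$perfusion$perfusion_ml_min_100g, 4),
      " ml/min/100g; mean probe IFP ", signif(mean(x$probe_ifp), 4), " mmHg\n", sep = "")
  invisible(x)
}

#' Run a replicate ensemble over boundary seeds
#'
#' Repeats the baseline workflow with identical configuration but different
#' boundary-assignment seeds, quantifying the variability induced by the
#' stochastic boundary conditions: per-node pressure standard deviations
#' and ensemble radial profiles.
#'
#' @param config A [run_config()]; its `seed` is replaced per replicate.
#' @param seeds Integer vector of replicate seeds.
#' @param fixed_network If `TRUE` (default) the network is generated once
#'   from the first seed and shared; only the boundary assignment varies.
#' @return A list of class `replicate_ensemble`: `summary` (per-seed
#'   tibble), `pressure_sd` (per-node tibble), `ensemble_profiles`
#'   (mean/sd of per-replicate bin means), `runs`.
#' @export
run_replicates <- function(config = run_config(), seeds = 1:3, fixed_network = TRUE) {
  stopifnot(length(seeds) >= 1L)
  runs <- list()
  shared_path <- NULL
  for (i in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    if (fixed_network && is.null(cfg$network$path)) {
      if (is.null(shared_path)) {
        net0 <- make_fixture(synthetic_spec(
          kind = cfg$network$kind, extent_um = cfg$network$extent_um,
          diameter_mean_um = cfg$network$diameter_mean_um,
          diameter_sd_um = cfg$network$diameter_sd_um,
          branch_length_um = cfg$network$branch_length_um,
          density_pct = cfg$network$density_pct, k = cfg$network$k,
          seed = config$seed
        ))
        shared_path <- tempfile("tf_net_")
        write_network(net0, shared_path, "csv")
      }
      cfg$network$path <- shared_path
      cfg$network$dialect <- "csv"
    }
    runs[[i]] <- run_baseline(cfg)
  }
  press <- vapply(runs, function(r) r$flow$nodes$pressure_mmHg,
                  numeric(nrow(runs[[1]]$flow$nodes)))
  press <- matrix(press, ncol = length(runs))
  summary <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    tibble::tibble(
      seed = seeds[i],
      perfusion_ml_min_100g = r$perfusion$perfusion_ml_min_100g,
      mean_pressure_mmHg = mean(r$flow$nodes$pressure_mmHg),
      mean_ifp_mmHg = mean(r$probe_ifp),
      mean_ifv_um_s = mean(r$probe_ifv),
      coupling_iterations = r$coupling$iterations,
      converged = r$coupling$converged
    )
  }))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  pressure_sd <- tibble::tibble(
    node = runs[[1]]$flow$nodes$id,
    sd_mmHg = apply(press, 1L, sd0)
  )
  prof <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    dplyr::mutate(runs[[i]]$profiles, seed = seeds[i])
  }))
  ensemble_profiles <- prof |>
    dplyr::group_by(.data$quantity, .data$bin, .data$r_mid) |>
    dplyr::summarise(mean = mean(.data$mean), sd = sd0(.data$mean),
                     n = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, pressure_sd = pressure_sd,
                 ensemble_profiles = ensemble_profiles, runs = runs),
            class = "replicate_ensemble")
}
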