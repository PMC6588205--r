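# Spatial summaries and therapy scenarios: radial profiles against
# normalised tumour radius, planar perfusion maps, source/sink balance,
# interstitial-parameter sweeps, and radially ramped vascular-normalization.

#' Radial profile of a scalar field
#'
#' Bins point values by normalised tumour radius (0 = hull centroid,
#' 1 = surface) and reports per-bin mean, standard deviation and count.
#' Points outside the hull (normalised radius > 1) are dropped.
#'
#' @param points n x 3 matrix (micron).
#' @param values Numeric vector, one per point.
#' @param hull A `tumour_hull`.
#' @param n_bins Number of equal-width bins on `[0, 1]` (default 10).
#' @return A tibble of class `radial_profile`: `bin`, `r_mid`, `mean`,
#'   `sd`, `n` (empty bins report `NaN` mean and `n = 0`).
#' @export
radial_profile <- function(points, values, hull, n_bins = 10L) {
  points <- rbind(points)
  stopifnot(nrow(points) == length(values))
  r <- normalised_radius(points, hull)
  keep <- r <= 1 + 1e-9
  r <- pmin(r[keep], 1)
  values <- values[keep]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        r_mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2)
  agg <- tibble::tibble(bin = bin, v = values) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$v),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$v), 0),
                     n = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin")
  out$mean[is.na(out$n)] <- NaN
  out$sd[is.na(out$n)] <- NaN
  out$n[is.na(out$n)] <- 0L
  class(out) <- c("radial_profile", class(out))
  out
}

#' Rasterise sampled values into a planar pixel map
#'
#' Aggregates sample points into isotropic square pixels in a coordinate
#' plane (per-pixel mean), emulating imaging-style perfusion/IFP maps. The
#' caller supplies the samples: interstitial fields are typically sampled
#' on a regular grid in a slab about the plane, vascular perfusion density
#' from segment midpoints weighted by |flow|.
#'
#' @param points n x 3 matrix (micron).
#' @param values Numeric vector, one per point.
#' @param pixel_um Pixel width (default 140 um).
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param at Plane offset (micron) along the remaining axis.
#' @param slab_um Slab thickness about `at` within which samples are kept
#'   (default `pixel_um`).
#' @return A tibble: `px`, `py` (pixel-centre coordinates, micron),
#'   `value` (per-pixel mean), `n`.
#' @export
rasterize_field <- function(points, values, pixel_um = 140, plane = c("xy", "xz", "yz"),
                            at = 0, slab_um = pixel_um) {
  plane <- match.arg(plane)
  points <- rbind(points)
  ax <- switch(plane, xy = c(1L, 2L, 3L), xz = c(1L, 3L, 2L), yz = c(2L, 3L, 1L))
  keep <- abs(points[, ax[3]] - at) <= slab_um / 2
  pts <- points[keep, , drop = FALSE]
  vals <- values[keep]
  if (!length(vals)) return(tibble::tibble(px = numeric(), py = numeric(),
                                           value = numeric(), n = integer()))
  ix <- floor(pts[, ax[1]] / pixel_um)
  iy <- floor(pts[, ax[2]] / pixel_um)
  tibble::tibble(ix = ix, iy = iy, v = vals) |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(value = mean(.data$v), n = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(px = (.data$ix + 0.5) * pixel_um,
                     py = (.data$iy + 0.5) * pixel_um,
                     value = .data$value, n = .data$n)
}

#' Radial source/sink-balance profile
#'
#' Per radial bin, the ratio `(n - m)/(n + m)` between the counts of
#' sources (`q > 0`) and sinks (`q < 0`); +1 means all sources, -1 all
#' sinks, 0 parity. Zero-strength sources count in neither.
#'
#' @param field An `interstitial_field` with solved strengths.
#' @param hull A `tumour_hull`.
#' @param n_bins Number of radial bins (default 10).
#' @return A tibble: `bin`, `r_mid`, `n_sources`, `n_sinks`, `ratio`
#'   (`NaN` for empty bins).
#' @export
source_sink_ratio_profile <- function(field, hull, n_bins = 10L) {
  src <- field$sources
  r <- pmin(normalised_radius(cbind(src$x, src$y, src$z), hull), 1)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        r_mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2)
  agg <- tibble::tibble(bin = bin, q = src$q_cm3_s) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_sources = sum(.data$q > 0), n_sinks = sum(.data$q < 0),
                     .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin")
  out$n_sources[is.na(out$n_sources)] <- 0L
  out$n_sinks[is.na(out$n_sinks)] <- 0L
  tot <- out$n_sources + out$n_sinks
  out$ratio <- ifelse(tot > 0, (out$n_sources - out$n_sinks) / tot, NaN)
  out
}

#' Sweep an interstitial parameter over the coupled solve
#'
#' Re-runs the coupled vascular/interstitial solve for each value of one
#' parameter on a fixed network, boundary-condition realisation and source
#' distribution (same seed throughout), and emits IFP and IFV radial
#' profiles per value. Isolates parameter effects from boundary-condition
#' randomness.
#'
#' @param network A `vascular_network`.
#' @param flow The baseline `flow_solution` (its boundary realisation is
#'   reused for every value).
#' @param hull A `tumour_hull`.
#' @param parameter One of `"p_inf"`, `"sigma"`, `"L_p"`, `"kappa"`,
#'   `"delta"`, `"r0_scale"`.
#' @param values Numeric vector of parameter values.
#' @param params Baseline [interstitial_params()].
#' @param delta_um Source spacing (micron) for the baseline.
#' @param probe_points Points (micron) at which IFP/IFV are profiled;
#'   default is a seeded uniform sample inside the hull.
#' @param n_bins Radial bins.
#' @param tolerance_ul_min,max_iter Passed to [couple()].
#' @return A tibble: `parameter`, `value`, `quantity` ("ifp_mmHg" or
#'   `"ifv_um_s"`), and the radial-profile columns.
#' @export
sweep_parameter <- function(network, flow, hull,
                            parameter = c("p_inf", "sigma", "L_p", "kappa",
                                          "delta", "r0_scale"),
                            values, params = interstitial_params(),
                            delta_um = 50, probe_points = NULL, n_bins = 10L,
                            tolerance_ul_min = 1e-6, max_iter = 50L) {
  parameter <- match.arg(parameter)
  if (is.null(probe_points)) probe_points <- hull_probe_points(hull, 800L, seed = 421L)
  out <- list()
  for (v in values) {
    p <- params
    delta_v <- delta_um
    r0_scale <- 1
    switch(parameter,
      p_inf = { p$p_inf_mmHg <- v },
      sigma = { p$sigma <- v },
      L_p = { p$L_p <- v },
      kappa = { p$kappa <- v },
      delta = { delta_v <- v },
      r0_scale = { r0_scale <- v }
    )
    sources <- distribute_sources(network, flow, delta_v)
    if (r0_scale != 1) sources$r0_um <- sources$r0_um * r0_scale
    cp <- couple(network, flow, sources, p, tolerance_ul_min = tolerance_ul_min,
                 max_iter = max_iter)
    ifp <- evaluate_ifp(probe_points, cp$field)
    ifv <- sqrt(rowSums(evaluate_ifv(probe_points, cp$field)^2))
    prof_p <- radial_profile(probe_points, ifp, hull, n_bins)
    prof_v <- radial_profile(probe_points, ifv, hull, n_bins)
    prof_p$quantity <- "ifp_mmHg"
    prof_v$quantity <- "ifv_um_s"
    pr <- dplyr::bind_rows(prof_p, prof_v)
    pr$parameter <- parameter
    pr$value <- v
    out[[length(out) + 1L]] <- pr
  }
  dplyr::bind_rows(out) |>
    dplyr::select("parameter", "value", "quantity", dplyr::everything())
}

# seeded uniform sample of points inside the hull (rejection from bbox)
hull_probe_points <- function(hull, n, seed = 421L) {
  lo <- apply(hull$vertices, 2L, min)
  hi <- apply(hull$vertices, 2L, max)
  with_seed(seed, {
    pts <- matrix(NA_real_, 0L, 3L)
    while (nrow(pts) < n) {
      cand <- cbind(stats::runif(2L * n, lo[1], hi[1]),
                    stats::runif(2L * n, lo[2], hi[2]),
                    stats::runif(2L * n, lo[3], hi[3]))
      pts <- rbind(pts, cand[in_hull(hull, cand), , drop = FALSE])
    }
    pts[seq_len(n), , drop = FALSE]
  })
}

#' Vascular-normalization scenario
#'
#' Therapy scenario in which treatment effectiveness ramps linearly with
#' normalised tumour radius (ineffective at the core, fully effective at
#' the periphery): vessel diameters shrink towards `d / diameter_factor`,
#' and wall conductance, reflection coefficient and interstitial
#' conductivity ramp towards physiological endpoint values. Each change is
#' applied only if its flag is set.
#'
#' @param diameter_factor Peripheral diameter reduction factor (default
#'   1.99).
#' @param L_p_norm Normalized wall conductance endpoint (default 0.44e-7
#'   cm/mmHg/s).
#' @param sigma_norm Normalized reflection coefficient endpoint (default
#'   0.91).
#' @param kappa_norm Normalized interstitial conductivity endpoint (default
#'   8.53e-9 cm2/mmHg/s).
#' @param normalize_diameter,normalize_L_p,normalize_sigma,normalize_kappa
#'   Flags selecting which parameters to ramp.
#' @return A list of class `normalization_scenario`.
#' @export
normalization_scenario <- function(diameter_factor = 1.99, L_p_norm = 0.44e-7,
                                   sigma_norm = 0.91, kappa_norm = 8.53e-9,
                                   normalize_diameter = TRUE, normalize_L_p = TRUE,
                                   normalize_sigma = TRUE, normalize_kappa = FALSE) {
  stopifnot(diameter_factor >= 1)
  structure(list(diameter_factor = diameter_factor, L_p_norm = L_p_norm,
                 sigma_norm = sigma_norm, kappa_norm = kappa_norm,
                 normalize_diameter = normalize_diameter,
                 normalize_L_p = normalize_L_p,
                 normalize_sigma = normalize_sigma,
                 normalize_kappa = normalize_kappa),
            class = "normalization_scenario")
}

#' Apply a normalization scenario to a network
#'
#' Segment diameters are scaled by `1 - rho (1 - 1/factor)` at the
#' segment-midpoint normalised radius `rho`; the per-source interstitial
#' parameters ramp linearly from their baseline value at the core to the
#' scenario endpoint at the periphery. With all flags off this is the
#' identity.
#'
#' @param network A `vascular_network`.
#' @param params Baseline [interstitial_params()].
#' @param scenario A [normalization_scenario()].
#' @param hull A `tumour_hull` defining the normalised radius.
#' @return A list: `network` (diameters modified if flagged) and
#'   `source_params(points_um)` — a function returning a tibble of
#'   per-source `L_p`, `sigma`, `kappa` columns at given positions, to be
#'   written into a `source_set`.
#' @export
apply_normalization <- function(network, params, scenario, hull) {
  xyz <- node_coords(network)
  segs <- network$segments
  mid <- (xyz[segs$from, , drop = FALSE] + xyz[segs$to, , drop = FALSE]) / 2
  rho_seg <- pmin(normalised_radius(mid, hull), 1)
  net2 <- network
  if (scenario$normalize_diameter) {
    net2$segments$diameter <- segs$diameter *
      (1 - rho_seg * (1 - 1 / scenario$diameter_factor))
  }
  source_params <- function(points_um) {
    rho <- pmin(normalised_radius(points_um, hull), 1)
    tibble::tibble(
      L_p = if (scenario$normalize_L_p)
        params$L_p + rho * (scenario$L_p_norm - params$L_p) else rep(NA_real_, length(rho)),
      sigma = if (scenario$normalize_sigma)
        params$sigma + rho * (scenario$sigma_norm - params$sigma) else rep(NA_real_, length(rho)),
      kappa = if (scenario$normalize_kappa)
        params$kappa + rho * (scenario$kappa_norm - params$kappa) else rep(NA_real_, length(rho))
    )
  }
  list(network = net2, source_params = source_params)
}
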