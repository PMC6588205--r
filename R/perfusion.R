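# Perfusion estimation over the tumour hull: a paired offset surface gives
# normal pressure gradients (hence Darcy velocities) across the tumour
# boundary, surface spheres turn vertex velocities into fluxes, and the
# vascular inlets at surface boundary nodes complete the total.

#' Normal interstitial velocities across the tumour surface
#'
#' For each hull vertex, a partner point is placed a `gap_um` outward along
#' the vertex normal; the pressure difference across the pair gives the
#' normal Darcy velocity. Positive values mean flow into the tumour.
#'
#' @param hull A `tumour_hull` (subdivide for resolution).
#' @param field An `interstitial_field`.
#' @param gap_um Gap between the paired surfaces (default 10 um).
#' @return A tibble: vertex index, position, `v_n_um_s` (signed, inward
#'   positive).
#' @export
paired_surface_velocities <- function(hull, field, gap_um = 10) {
  inner <- hull$vertices
  outer <- inner + gap_um * hull$vertex_normals
  p_in <- evaluate_ifp(inner, field)
  p_out <- evaluate_ifp(outer, field)
  kappa <- field$params$kappa
  gap_cm <- gap_um * tf_units$um_to_cm
  # u . (-n) = kappa dp/dn; inward-positive velocity
  v_n_cm_s <- kappa * (p_out - p_in) / gap_cm
  tibble::tibble(vertex = seq_len(nrow(inner)),
                 x = inner[, 1], y = inner[, 2], z = inner[, 3],
                 v_n_um_s = v_n_cm_s * tf_units$cm_s_to_um_s)
}

#' Pack non-overlapping spheres on the hull surface
#'
#' Greedy packing over the hull vertices in decreasing local-spacing order:
#' each sphere's radius is the distance remaining to the nearest
#' already-packed sphere, capped at half the mean incident edge length of
#' its vertex. No two spheres overlap; vertices left with no room are
#' skipped. The packing is deterministic for a fixed mesh.
#'
#' @param hull A `tumour_hull`.
#' @return A tibble: vertex, position, `radius_um`.
#' @export
sphere_pack_surface <- function(hull) {
  v <- hull$vertices
  f <- hull$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  elen <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] - v[edges[, 2], , drop = FALSE])^2))
  spacing <- as.numeric(tabulate2(c(edges[, 1], edges[, 2]), rep(elen, 2), nrow(v)) /
                          pmax(tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(v)), 1L))
  cap <- spacing / 2
  ord <- order(cap, decreasing = TRUE)
  centres <- matrix(NA_real_, 0L, 3L)
  radii <- numeric(0)
  keep <- integer(0)
  for (i in ord) {
    r <- cap[i]
    if (nrow(centres)) {
      d <- sqrt(rowSums(sweep(centres, 2L, v[i, ])^2))
      r <- min(r, min(d - radii))
    }
    if (r <= 0) next
    centres <- rbind(centres, v[i, ])
    radii <- c(radii, r)
    keep <- c(keep, i)
  }
  tibble::tibble(vertex = keep, x = centres[, 1], y = centres[, 2], z = centres[, 3],
                 radius_um = radii)
}

#' Total tissue perfusion
#'
#' Sums the vascular inflow at surface boundary nodes and the interstitial
#' inflow through the hull surface (each inflowing packed sphere
#' contributes its normal velocity times its great-circle area), normalised
#' by tumour mass (hull volume times tissue density). By default only
#' inflow contributes (`mode = "inflow"`); `mode = "net"` subtracts
#' outflow.
#'
#' @param flow A `flow_solution`.
#' @param hull A `tumour_hull` (subdivided for a resolved surface).
#' @param field An `interstitial_field`, or `NULL` to count only the
#'   vascular component.
#' @param network The `vascular_network`.
#' @param gap_um Paired-surface gap (micron).
#' @param density_g_cm3 Tissue density converting volume to mass (default
#'   1, water).
#' @param mode `"inflow"` (only inflowing spheres/nodes) or `"net"`.
#' @param depth_tolerance_um Surface classification tolerance.
#' @return A one-row tibble of class `perfusion_result`:
#'   `vascular_ml_min`, `interstitial_ml_min`, `mass_g`,
#'   `perfusion_ml_min_100g`.
#' @export
total_perfusion <- function(flow, hull, field = NULL, network,
                            gap_um = 10, density_g_cm3 = 1,
                            mode = c("inflow", "net"),
                            depth_tolerance_um = NULL) {
  mode <- match.arg(mode)
  cls <- classify_surface_nodes(network, hull, depth_tolerance_um)
  q0 <- flow$nodes$boundary_flux_nl_min[cls$surface] * 1e-6  # nl/min -> ml/min
  vascular <- if (mode == "inflow") sum(pmax(q0, 0)) else sum(q0)
  interstitial <- 0
  if (!is.null(field)) {
    vel <- paired_surface_velocities(hull, field, gap_um)
    packing <- sphere_pack_surface(hull)
    v_n <- vel$v_n_um_s[packing$vertex] * 1e-4 * 60  # um/s -> cm/min
    area_cm2 <- pi * (packing$radius_um * tf_units$um_to_cm)^2
    # the discs are a quadrature rule over the hull surface: non-overlapping
    # packings leave a fixed porosity (~20% even on regular meshes), so the
    # weights are normalised to the true surface area to keep the flux
    # estimate consistent under mesh refinement
    w <- area_cm2 * hull$area_cm2 / sum(area_cm2)
    flux <- v_n * w                                  # cm3/min = ml/min
    interstitial <- if (mode == "inflow") sum(pmax(flux, 0)) else sum(flux)
  }
  mass_g <- hull$volume_cm3 * density_g_cm3
  out <- tibble::tibble(
    vascular_ml_min = vascular,
    interstitial_ml_min = interstitial,
    mass_g = mass_g,
    perfusion_ml_min_100g = 100 * (vascular + interstitial) / mass_g
  )
  class(out) <- c("perfusion_result", class(out))
  out
}
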