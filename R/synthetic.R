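# Seeded generators of test networks. The tumour-like generator emulates
# summary statistics of real segmented tumour networks (mean vessel
# diameter, branch spacing, vascular density); it is test scaffolding with
# controlled statistics, not a mechanistic angiogenesis model.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic network
#'
#' @param kind One of `"single_vessel"`, `"y_junction"`, `"lattice3d"`,
#'   `"tumour_like"`.
#' @param extent_um Domain extent (full axes) in micron; scalar or length 3.
#' @param diameter_mean_um,diameter_sd_um Target vessel diameter
#'   distribution (micron); defaults follow a low-density colorectal
#'   xenograft morphology (8.9 +/- 2.8 um).
#' @param branch_length_um Target mean branching-vessel spacing (micron,
#'   default 88.8).
#' @param density_pct Target vascular density, percent of domain volume
#'   occupied by vessel lumen (default 0.37).
#' @param k Lattice nodes per axis (lattice3d only, default 3).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("single_vessel", "y_junction", "lattice3d", "tumour_like"),
                           extent_um = 2000, diameter_mean_um = 8.9,
                           diameter_sd_um = 2.8, branch_length_um = 88.8,
                           density_pct = 0.37, k = 3L, seed = 1L) {
  kind <- match.arg(kind)
  extent_um <- rep_len(extent_um, 3L)
  stopifnot(all(extent_um > 0), diameter_mean_um > 0, branch_length_um > 0,
            density_pct > 0, density_pct < 100, k >= 2L)
  structure(list(kind = kind, extent_um = extent_um,
                 diameter_mean_um = diameter_mean_um, diameter_sd_um = diameter_sd_um,
                 branch_length_um = branch_length_um, density_pct = density_pct,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic vascular network
#'
#' Deterministic (`single_vessel`, `y_junction`, `lattice3d`) and
#' seeded-stochastic (`tumour_like`) fixtures. The tumour-like generator
#' places a jittered cubic lattice inside an ellipsoidal domain, retains a
#' random spanning tree plus random extra edges until the target vascular
#' density is met, and draws i.i.d. log-normal diameters rescaled to the
#' target mean. Identical seeds give identical networks.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `vascular_network`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  switch(spec$kind,
    single_vessel = make_single_vessel(spec),
    y_junction = make_y_junction(spec),
    lattice3d = make_lattice3d(spec),
    tumour_like = with_seed(spec$seed, make_tumour_like(spec))
  )
}

make_single_vessel <- function(spec) {
  l <- spec$branch_length_um
  vascular_network(
    data.frame(id = 1:2, x = c(0, l), y = 0, z = 0),
    data.frame(id = 1, from = 1, to = 2, diameter = spec$diameter_mean_um, length = l)
  )
}

make_y_junction <- function(spec) {
  l <- spec$branch_length_um
  d <- spec$diameter_mean_um
  s3 <- sqrt(3) / 2
  vascular_network(
    data.frame(id = 1:4,
               x = c(0, 0, l * s3, -l * s3),
               y = c(l, 0, -l / 2, -l / 2), z = 0),
    data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
               diameter = c(d, d * 2^(-1 / 3), d * 2^(-1 / 3)), length = l)
  )
}

make_lattice3d <- function(spec) {
  k <- spec$k
  h <- spec$branch_length_um
  grid <- expand.grid(ix = seq_len(k), iy = seq_len(k), iz = seq_len(k))
  nodes <- data.frame(id = seq_len(nrow(grid)),
                      x = (grid$ix - 1) * h, y = (grid$iy - 1) * h, z = (grid$iz - 1) * h)
  node_at <- function(ix, iy, iz) (iz - 1) * k * k + (iy - 1) * k + ix
  edges <- list()
  for (ax in 1:3) {
    g2 <- grid[grid[[ax]] < k, ]
    to <- g2
    to[[ax]] <- to[[ax]] + 1L
    edges[[ax]] <- cbind(node_at(g2$ix, g2$iy, g2$iz), node_at(to$ix, to$iy, to$iz))
  }
  em <- do.call(rbind, edges)
  vascular_network(
    nodes,
    data.frame(id = seq_len(nrow(em)), from = em[, 1], to = em[, 2],
               diameter = spec$diameter_mean_um, length = h)
  )
}

# Tumour-like generator: bifurcating trees grown inward from roots on the
# ellipsoid surface (Murray-type 2^(-1/3) diameter taper with log-normal
# noise), joined by a peritumoural ring for connectivity. Tips crossing the
# surface are clipped onto it and become surface boundary nodes; growth
# stops at the target vascular density. A single recalibration pass pins
# the realised branch length and density; diameters are rescaled to the
# target mean.
make_tumour_like <- function(spec) {
  net <- make_tumour_like_once(spec, spec$branch_length_um, spec$density_pct)
  realised_bl <- mean(network_branches(net)$length)
  # density is reported against the convex hull of the nodes, which is
  # tighter than the growth ellipsoid; recalibrate against the hull figure
  realised_rho <- network_statistics(net)$vascular_density_pct
  bl2 <- spec$branch_length_um^2 / realised_bl
  rho2 <- spec$density_pct^2 / realised_rho
  if (abs(realised_bl / spec$branch_length_um - 1) > 0.02 ||
        abs(realised_rho / spec$density_pct - 1) > 0.02) {
    net2 <- try(make_tumour_like_once(spec, bl2, rho2), silent = TRUE)
    if (!inherits(net2, "try-error")) net <- net2
  }
  net
}

make_tumour_like_once <- function(spec, branch_draw_um, density_draw_pct) {
  set.seed(spec$seed)  # each pass draws the same substream
  semi <- spec$extent_um / 2
  domain_vol <- 4 / 3 * pi * prod(semi)
  target_vol <- density_draw_pct / 100 * domain_vol
  if (spec$density_pct >= 20) {
    stop("unachievable density: vessel volume would exceed the domain")
  }
  bl_sd <- 0.45 * spec$branch_length_um
  d_floor <- 2.5
  n_roots <- 10L
  max_seg <- 200000L

  scaled_r <- function(p) sqrt(sum((p / semi)^2))
  unit <- function(v) v / sqrt(sum(v^2))

  # storage (grown dynamically in chunks is unnecessary at this scale)
  nx <- ny <- nz <- numeric(0)
  sfrom <- sto <- integer(0)
  sdia <- slen <- numeric(0)
  add_node <- function(p) {
    nx[length(nx) + 1L] <<- p[1]; ny[length(ny) + 1L] <<- p[2]; nz[length(nz) + 1L] <<- p[3]
    length(nx)
  }
  add_seg <- function(a, b, d, l) {
    sfrom[length(sfrom) + 1L] <<- a; sto[length(sto) + 1L] <<- b
    sdia[length(sdia) + 1L] <<- d; slen[length(slen) + 1L] <<- l
  }

  # roots on the ellipsoid surface, joined into a peritumoural ring
  roots_u <- fibonacci_sphere(n_roots)
  root_pos <- sweep(roots_u, 2L, semi, "*")
  root_ids <- integer(n_roots)
  for (i in seq_len(n_roots)) root_ids[i] <- add_node(root_pos[i, ])
  ring_d <- 1.6 * spec$diameter_mean_um
  for (i in seq_len(n_roots)) {
    j <- if (i == n_roots) 1L else i + 1L
    l <- sqrt(sum((root_pos[i, ] - root_pos[j, ])^2))
    add_seg(root_ids[i], root_ids[j], ring_d, l)
  }
  # diameters are rescaled to the target mean at the end, so the stopping
  # rule tracks the projected post-rescale volume
  proj_vol <- function() {
    c_scale <- spec$diameter_mean_um / mean(sdia)
    (pi / 4) * c_scale^2 * sum(sdia^2 * slen)
  }
  vol <- proj_vol()

  # tip queue: trees grow breadth-first, interleaved across roots
  root_d <- 2.2 * spec$diameter_mean_um * exp(stats::rnorm(n_roots, 0, 0.1))
  tips <- lapply(seq_len(n_roots), function(i) {
    inward <- unit(-root_pos[i, ] / semi^2)  # inward ellipsoid normal
    list(node = root_ids[i], dir = unit(inward + stats::rnorm(3, 0, 0.2)),
         d = root_d[i])
  })
  p_term <- 0.12
  exhausted <- FALSE
  while (vol < target_vol) {
    if (length(tips) == 0L) {
      # angiogenic re-sprouting: new tips bud from existing nodes so any
      # realistic density target is reachable without losing connectivity
      budding <- sample(length(nx), min(20L, length(nx)))
      tips <- lapply(budding, function(b) {
        list(node = b, dir = unit(stats::rnorm(3)),
             d = 1.3 * spec$diameter_mean_um * exp(stats::rnorm(1, 0, 0.1)))
      })
    }
    if (length(sdia) > max_seg) { exhausted <- TRUE; break }
    tip <- tips[[1L]]
    tips <- tips[-1L]
    L <- max(0.25 * branch_draw_um,
             stats::rnorm(1, branch_draw_um, bl_sd * branch_draw_um / spec$branch_length_um))
    p0 <- c(nx[tip$node], ny[tip$node], nz[tip$node])
    p1 <- p0 + L * tip$dir
    at_surface <- FALSE
    if (scaled_r(p1) >= 0.995) {
      # clip onto the surface; the tip becomes a surface boundary node
      f <- function(t) scaled_r(p0 + t * L * tip$dir) - 0.995
      if (f(0) >= 0) next  # already at the surface; drop the tip
      t_hit <- stats::uniroot(f, c(0, 1))$root
      if (t_hit * L < 0.1 * branch_draw_um) next
      p1 <- p0 + t_hit * L * tip$dir
      L <- t_hit * L
      at_surface <- TRUE
    }
    n1 <- add_node(p1)
    add_seg(tip$node, n1, tip$d, L)
    vol <- proj_vol()
    if (at_surface) next
    if (stats::runif(1) < p_term) next  # blind end inside the tissue
    d_child <- tip$d * 2^(-1 / 3) * exp(stats::rnorm(2, 0, 0.15))
    for (cc in 1:2) {
      if (d_child[cc] < d_floor) next
      dir_c <- unit(tip$dir + stats::rnorm(3, 0, 0.55))
      tips[[length(tips) + 1L]] <- list(node = n1, dir = dir_c, d = d_child[cc])
    }
  }
  if (exhausted && vol < 0.9 * target_vol) {
    stop("unachievable density: segment cap reached at ",
         signif(100 * vol / domain_vol, 3), "% of domain volume")
  }
  sdia <- sdia * spec$diameter_mean_um / mean(sdia)  # pin the realised mean
  vascular_network(
    data.frame(id = seq_along(nx), x = nx, y = ny, z = nz),
    data.frame(id = seq_along(sdia), from = sfrom, to = sto,
               diameter = sdia, length = slen)
  )
}

# quasi-uniform points on a sphere (Fibonacci spiral)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Minimal configurations with known interstitial solutions
#'
#' Analytic test harnesses: a single regularized source at the origin, two
#' equal sources at mirror positions, and one source at the centre of a
#' spherical hull.
#'
#' @param name `"one_source"`, `"two_source_symmetric"` or
#'   `"central_source_sphere"`.
#' @param p_b_mmHg Vascular pressure assigned to each source (default 25).
#' @param r0_um Source (= vessel) radius in micron (default 5).
#' @return A list with `network` (a `vascular_network`), `sources` (a
#'   `source_set` stub with unsolved strengths) and, for the sphere case,
#'   `hull_points` (point cloud of the spherical surface, micron).
#' @export
reference_configuration <- function(name = c("one_source", "two_source_symmetric",
                                             "central_source_sphere"),
                                    p_b_mmHg = 25, r0_um = 5) {
  name <- match.arg(name)
  vessel <- function(x0, y0) {
    list(nodes = data.frame(id = 1:2, x = c(x0 - 25, x0 + 25), y = y0, z = 0),
         segs = data.frame(id = 1, from = 1, to = 2, diameter = 2 * r0_um, length = 50))
  }
  if (name == "one_source") {
    v <- vessel(0, 0)
    net <- vascular_network(v$nodes, v$segs)
    sources <- new_source_set(
      x = 0, y = 0, z = 0, r0_um = r0_um, rv_um = r0_um, l_um = 50,
      segment = 1L, p_b_mmHg = p_b_mmHg
    )
    list(network = net, sources = sources)
  } else if (name == "two_source_symmetric") {
    v1 <- vessel(-60, 0)
    v2 <- vessel(60, 0)
    v2$nodes$id <- 3:4
    v2$segs$id <- 2
    v2$segs$from <- 3
    v2$segs$to <- 4
    net <- vascular_network(rbind(v1$nodes, v2$nodes), rbind(v1$segs, v2$segs))
    sources <- new_source_set(
      x = c(-60, 60), y = c(0, 0), z = c(0, 0),
      r0_um = rep(r0_um, 2), rv_um = rep(r0_um, 2), l_um = c(50, 50),
      segment = 1:2, p_b_mmHg = rep(p_b_mmHg, 2)
    )
    list(network = net, sources = sources)
  } else {
    v <- vessel(0, 0)
    net <- vascular_network(v$nodes, v$segs)
    sources <- new_source_set(
      x = 0, y = 0, z = 0, r0_um = r0_um, rv_um = r0_um, l_um = 50,
      segment = 1L, p_b_mmHg = p_b_mmHg
    )
    list(network = net, sources = sources,
         hull_points = fibonacci_sphere(200, radius = 500))
  }
}
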