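# Convex hull of the node cloud defines the tumour surface and volume used
# for perfusion normalisation (mass = volume x density). Implemented as an
# incremental 3-D quickhull; faces are triangles oriented with outward
# normals. Midpoint 4:1 subdivision refines the surface for the paired
# pressure-gradient evaluation; on a convex polytope edge midpoints already
# lie on the hull boundary, so no projection step is needed.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# incremental convex hull; pts: n x 3 matrix. Returns list(vertices, faces)
# with faces indexing rows of pts, outward-oriented.
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs at least 4 points")
  scale <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (scale == 0) stop("degenerate input: all points coincide")
  eps <- 1e-9 * scale

  # initial simplex: extremes in x, farthest from line, farthest from plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  crossmat <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
                    rel[, 3] * d12[1] - rel[, 1] * d12[3],
                    rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dist_line <- sqrt(rowSums(crossmat^2))
  i3 <- which.max(dist_line)
  if (dist_line[i3] < eps) stop("degenerate input: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dist_plane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dist_plane)
  if (dist_plane[i4] < eps) stop("degenerate (coplanar) input")

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid0 <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nf <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nf * (centroid0 - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1L, orient))

  face_normal <- function(f) {
    nf <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nf
  }
  normals <- t(apply(faces, 1L, face_normal))
  offsets <- rowSums(normals * pts[faces[, 1], , drop = FALSE])

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    vis <- drop(normals %*% pts[p, ]) - offsets > eps
    if (!any(vis)) next
    vis_faces <- faces[vis, , drop = FALSE]
    # horizon: edges appearing exactly once among visible faces
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)], vis_faces[, c(3, 1)])
    keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[keys %in% names(which(table(keys) == 1L)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    normals <- normals[!vis, , drop = FALSE]
    offsets <- offsets[!vis]
    # new faces keep the winding of the horizon edge as seen from the old face
    new_faces <- cbind(horizon, p)
    new_normals <- t(apply(new_faces, 1L, face_normal))
    new_offsets <- rowSums(new_normals * pts[new_faces[, 1], , drop = FALSE])
    # reorient any face whose normal points at the interior reference point
    flip <- drop(new_normals %*% centroid0) - new_offsets > 0
    if (any(flip)) {
      new_faces[flip, ] <- new_faces[flip, c(2, 1, 3), drop = FALSE]
      new_normals[flip, ] <- -new_normals[flip, , drop = FALSE]
      new_offsets[flip] <- -new_offsets[flip]
    }
    faces <- rbind(faces, new_faces)
    normals <- rbind(normals, new_normals)
    offsets <- c(offsets, new_offsets)
  }
  used <- sort(unique(as.vector(faces)))
  remap <- match(seq_len(n), used)
  list(vertices = pts[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3L))
}

# one level of 4:1 midpoint subdivision of a triangle mesh
subdivide_mesh <- function(vertices, faces) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- edge_key(faces[, 1], faces[, 2])
  e2 <- edge_key(faces[, 2], faces[, 3])
  e3 <- edge_key(faces[, 3], faces[, 1])
  all_keys <- unique(c(e1, e2, e3))
  mid_idx <- nrow(vertices) + seq_along(all_keys)
  names(mid_idx) <- all_keys
  parse_mid <- function(keys) {
    ab <- do.call(rbind, strsplit(keys, " "))
    (vertices[as.integer(ab[, 1]), , drop = FALSE] +
       vertices[as.integer(ab[, 2]), , drop = FALSE]) / 2
  }
  mids <- parse_mid(all_keys)
  m1 <- mid_idx[e1]; m2 <- mid_idx[e2]; m3 <- mid_idx[e3]
  new_faces <- rbind(
    cbind(faces[, 1], m1, m3),
    cbind(m1, faces[, 2], m2),
    cbind(m3, m2, faces[, 3]),
    cbind(m1, m2, m3)
  )
  list(vertices = rbind(vertices, mids), faces = unname(new_faces))
}

#' Compute the tumour hull
#'
#' Builds the convex hull of a 3-D point cloud (typically all network node
#' positions), optionally refines the triangulation by midpoint 4:1
#' subdivision, and computes the enclosed volume by the divergence theorem.
#' The hull defines the tumour surface for perfusion estimation and the
#' normalisation radius for radial profiles.
#'
#' @param points n x 3 matrix of positions (micron), or a
#'   `vascular_network` whose nodes are used.
#' @param subdivisions Number of 4:1 subdivision passes applied to the hull
#'   triangulation (default 0).
#' @return A `tumour_hull`: list with `vertices` (micron), `faces`,
#'   `face_normals` (unit, outward), `vertex_normals` (unit, area-weighted),
#'   `centroid`, `volume_cm3`, `area_cm2`.
#' @export
compute_hull <- function(points, subdivisions = 0L) {
  if (inherits(points, "vascular_network")) points <- node_coords(points)
  hull <- convex_hull_3d(points)
  v <- hull$vertices
  f <- hull$faces
  for (i in seq_len(subdivisions)) {
    s <- subdivide_mesh(v, f)
    v <- s$vertices
    f <- s$faces
  }
  centroid <- colMeans(hull$vertices)
  a <- v[f[, 1], , drop = FALSE] - matrix(centroid, nrow(f), 3, byrow = TRUE)
  b <- v[f[, 2], , drop = FALSE] - matrix(centroid, nrow(f), 3, byrow = TRUE)
  cc <- v[f[, 3], , drop = FALSE] - matrix(centroid, nrow(f), 3, byrow = TRUE)
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  volume_um3 <- sum(det3) / 6
  fn <- cbind(
    (b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
    (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
    (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  )
  face_area2 <- sqrt(rowSums(fn^2))
  face_normals <- fn / face_area2
  vertex_normals <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    vertex_normals[, 1] <- vertex_normals[, 1] + tabulate2(f[, k], fn[, 1], nrow(v))
    vertex_normals[, 2] <- vertex_normals[, 2] + tabulate2(f[, k], fn[, 2], nrow(v))
    vertex_normals[, 3] <- vertex_normals[, 3] + tabulate2(f[, k], fn[, 3], nrow(v))
  }
  vertex_normals <- vertex_normals / pmax(sqrt(rowSums(vertex_normals^2)), 1e-300)
  structure(
    list(
      vertices = v, faces = f,
      face_normals = face_normals,
      vertex_normals = vertex_normals,
      centroid = centroid,
      volume_cm3 = volume_um3 * tf_units$um_to_cm^3,
      area_cm2 = sum(face_area2) / 2 * tf_units$um_to_cm^2
    ),
    class = "tumour_hull"
  )
}

# weighted tabulate: sum w over bins
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @method print tumour_hull
#' @export
print.tumour_hull <- function(x, ...) {
  cat("<tumour_hull> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, volume ", signif(x$volume_cm3, 4), " cm3\n", sep = "")
  invisible(x)
}

#' Test points for hull membership
#' @param hull A `tumour_hull`.
#' @param points n x 3 matrix (micron).
#' @param tol Slack in micron (positive admits points slightly outside).
#' @return Logical vector.
#' @export
in_hull <- function(hull, points, tol = 1e-6) {
  points <- rbind(points)
  d <- rowSums(hull$face_normals * hull$vertices[hull$faces[, 1], , drop = FALSE])
  inside <- rep(TRUE, nrow(points))
  proj <- points %*% t(hull$face_normals)
  for (jf in seq_along(d)) inside <- inside & (proj[, jf] <= d[jf] + tol)
  inside
}

#' Distance from the hull centroid to the surface along given directions
#' @param hull A `tumour_hull`.
#' @param dirs n x 3 matrix of directions (need not be unit).
#' @return Numeric vector of distances (micron) along each unit direction.
#' @export
hull_ray_distance <- function(hull, dirs) {
  dirs <- rbind(dirs)
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-300)
  N <- hull$face_normals
  d <- rowSums(N * hull$vertices[hull$faces[, 1], , drop = FALSE])
  num <- d - drop(N %*% hull$centroid)      # distance of each face plane from centroid
  den <- dirs %*% t(N)                      # n x F
  tt <- sweep(1 / den, 2L, num, "*")
  tt[den <= 1e-12] <- Inf
  apply(tt, 1L, min)
}

#' Normalised tumour radius of points
#'
#' Radius from the hull centroid divided by the centroid-to-surface distance
#' along the same ray, so 0 marks the tumour core and 1 the surface.
#'
#' @param points n x 3 matrix (micron).
#' @param hull A `tumour_hull`.
#' @return Numeric vector in `[0, Inf)` (values > 1 lie outside the hull).
#' @export
normalised_radius <- function(points, hull) {
  points <- rbind(points)
  rel <- sweep(points, 2L, hull$centroid)
  r <- sqrt(rowSums(rel^2))
  out <- numeric(nrow(points))
  nz <- r > 1e-12
  if (any(nz)) out[nz] <- r[nz] / hull_ray_distance(hull, rel[nz, , drop = FALSE])
  out
}
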