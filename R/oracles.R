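# Independent reference solutions for validating the Green's-function
# machinery: the closed-form single-source field, and a brute-force
# finite-difference Poisson solver (7-point Laplacian, conjugate
# gradients) with the regularized sources deposited as uniform spherical
# volumetric densities.

#' Analytic field of a single regularized source
#'
#' Closed form `p(x) = p_inf + q G(|x|; r0, kappa)` evaluated directly
#' (independent code path from the superposition evaluator).
#'
#' @param points n x 3 matrix (micron), relative to the source at `centre`.
#' @param q_cm3_s Source strength (cm3/s).
#' @param kappa Hydraulic conductivity (cm2/mmHg/s).
#' @param r0_um Source radius (micron).
#' @param p_inf_mmHg Far-field pressure (mmHg).
#' @param centre Source centre (micron).
#' @return Pressures (mmHg).
#' @export
analytic_single_source <- function(points, q_cm3_s, kappa, r0_um,
                                   p_inf_mmHg = 0, centre = c(0, 0, 0)) {
  points <- rbind(points)
  r_cm <- sqrt(rowSums(sweep(points, 2L, centre)^2)) * tf_units$um_to_cm
  r0 <- r0_um * tf_units$um_to_cm
  G <- ifelse(r_cm <= r0,
              (3 - (r_cm / r0)^2) / (8 * pi * kappa * r0),
              1 / (4 * pi * kappa * r_cm))
  p_inf_mmHg + q_cm3_s * G
}

#' Finite-difference Darcy oracle
#'
#' Solves `-kappa lap(p) = f` on a uniform grid over a box with Dirichlet
#' boundary values, where `f` deposits each source's strength uniformly
#' over its sphere (discretely renormalised so the deposited total equals
#' `q` exactly). `boundary = "superposition"` (default) sets the box faces
#' to the closed-form outer-branch kernel sum (exact when the faces lie
#' outside every source sphere), which keeps domain-truncation error out of
#' the comparison; `"far_field"` uses a uniform `p_inf`, adequate only when
#' the box is very large or the net source strength is near zero. The
#' symmetric positive-definite system is solved by conjugate gradients,
#' matrix-free.
#'
#' @param sources A `source_set` (or tibble with `x`, `y`, `z`, `r0_um`,
#'   `q_cm3_s`).
#' @param kappa Hydraulic conductivity (cm2/mmHg/s).
#' @param box 2 x 3 matrix: rows are the lower/upper corners (micron).
#' @param h_um Grid spacing (micron); should be below the smallest source
#'   radius to resolve the spheres.
#' @param p_inf_mmHg Far-field pressure.
#' @param boundary `"superposition"` or `"far_field"`.
#' @param tol CG relative residual tolerance.
#' @return A list of class `grid_solution`: coordinate vectors `x`, `y`,
#'   `z` (micron), 3-D pressure array `p` (mmHg), `h_um`, `residual`,
#'   `iterations`.
#' @export
fd_darcy_solve <- function(sources, kappa, box, h_um, p_inf_mmHg = 0,
                           boundary = c("superposition", "far_field"),
                           tol = 1e-8) {
  boundary <- match.arg(boundary)
  box <- rbind(box)
  stopifnot(nrow(box) == 2L, ncol(box) == 3L, h_um > 0)
  margin <- apply(cbind(sources$x - box[1, 1], box[2, 1] - sources$x,
                        sources$y - box[1, 2], box[2, 2] - sources$y,
                        sources$z - box[1, 3], box[2, 3] - sources$z), 1L, min)
  if (any(margin < 2 * sources$r0_um)) {
    warning("box margin under two source radii; truncation error may dominate")
  }
  nx <- round((box[2, 1] - box[1, 1]) / h_um) + 1L
  ny <- round((box[2, 2] - box[1, 2]) / h_um) + 1L
  nz <- round((box[2, 3] - box[1, 3]) / h_um) + 1L
  xs <- box[1, 1] + (seq_len(nx) - 1L) * h_um
  ys <- box[1, 2] + (seq_len(ny) - 1L) * h_um
  zs <- box[1, 3] + (seq_len(nz) - 1L) * h_um
  h_cm <- h_um * tf_units$um_to_cm

  # volumetric source density (mmHg-compatible: f has units of q / volume)
  f <- array(0, c(nx, ny, nz))
  for (s in seq_len(nrow(sources))) {
    dx2 <- (xs - sources$x[s])^2
    dy2 <- (ys - sources$y[s])^2
    dz2 <- (zs - sources$z[s])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= sources$r0_um[s]^2
    ncell <- sum(inside)
    if (ncell == 0L) stop("grid spacing too coarse to resolve source ", s)
    f[inside] <- f[inside] + sources$q_cm3_s[s] / (ncell * h_cm^3)
  }

  # Dirichlet boundary values
  pbar <- array(0, c(nx, ny, nz))  # p - p_inf
  if (boundary == "superposition") {
    set_face <- function(ix, iy, iz) {
      pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
      val <- rep(0, nrow(pts))
      for (s in seq_len(nrow(sources))) {
        r_cm <- sqrt((pts[, 1] - sources$x[s])^2 + (pts[, 2] - sources$y[s])^2 +
                       (pts[, 3] - sources$z[s])^2) * tf_units$um_to_cm
        val <- val + sources$q_cm3_s[s] / (4 * pi * kappa * pmax(r_cm, 1e-300))
      }
      pbar[ix, iy, iz] <<- array(val, c(length(ix), length(iy), length(iz)))
    }
    set_face(1L, seq_len(ny), seq_len(nz)); set_face(nx, seq_len(ny), seq_len(nz))
    set_face(seq_len(nx), 1L, seq_len(nz)); set_face(seq_len(nx), ny, seq_len(nz))
    set_face(seq_len(nx), seq_len(ny), 1L); set_face(seq_len(nx), seq_len(ny), nz)
  }

  ii <- 2:(nx - 1L); jj <- 2:(ny - 1L); kk <- 2:(nz - 1L)
  # operator A u = -kappa * discrete Laplacian(u) on the interior, with u = 0
  # on the boundary ring (boundary data folded into the RHS)
  apply_A <- function(u) {
    U <- array(0, c(nx, ny, nz))
    U[ii, jj, kk] <- u
    (kappa / h_cm^2) * (6 * U[ii, jj, kk] -
      U[ii - 1L, jj, kk] - U[ii + 1L, jj, kk] -
      U[ii, jj - 1L, kk] - U[ii, jj + 1L, kk] -
      U[ii, jj, kk - 1L] - U[ii, jj, kk + 1L])
  }
  Ub <- pbar
  Ub[ii, jj, kk] <- 0
  rhs <- f[ii, jj, kk] + (kappa / h_cm^2) * (
    Ub[ii - 1L, jj, kk] + Ub[ii + 1L, jj, kk] +
    Ub[ii, jj - 1L, kk] + Ub[ii, jj + 1L, kk] +
    Ub[ii, jj, kk - 1L] + Ub[ii, jj, kk + 1L])

  u <- array(0, dim(rhs))
  r <- rhs - apply_A(u)
  p_dir <- r
  rs <- sum(r * r)
  bnorm <- max(sqrt(sum(rhs * rhs)), 1e-300)
  it <- 0L
  maxit <- 10000L
  while (sqrt(rs) / bnorm > tol && it < maxit) {
    it <- it + 1L
    Ap <- apply_A(p_dir)
    alpha <- rs / sum(p_dir * Ap)
    u <- u + alpha * p_dir
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p_dir <- r + (rs_new / rs) * p_dir
    rs <- rs_new
  }
  if (it >= maxit) warning("CG hit the iteration cap; residual ", signif(sqrt(rs) / bnorm, 3))
  pbar[ii, jj, kk] <- u
  structure(list(x = xs, y = ys, z = zs, p = pbar + p_inf_mmHg, h_um = h_um,
                 residual = sqrt(rs) / bnorm, iterations = it),
            class = "grid_solution")
}

#' Interpolate a grid solution at arbitrary points
#'
#' Trilinear interpolation of a `grid_solution` pressure array.
#'
#' @param grid A `grid_solution`.
#' @param points n x 3 matrix (micron) inside the grid box.
#' @return Pressures (mmHg).
#' @export
grid_interpolate <- function(grid, points) {
  points <- rbind(points)
  h <- grid$h_um
  fx <- (points[, 1] - grid$x[1]) / h
  fy <- (points[, 2] - grid$y[1]) / h
  fz <- (points[, 3] - grid$z[1]) / h
  i0 <- pmin(pmax(floor(fx), 0), length(grid$x) - 2L)
  j0 <- pmin(pmax(floor(fy), 0), length(grid$y) - 2L)
  k0 <- pmin(pmax(floor(fz), 0), length(grid$z) - 2L)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  g <- function(di, dj, dk) {
    grid$p[cbind(i0 + 1L + di, j0 + 1L + dj, k0 + 1L + dk)]
  }
  (1 - tx) * (1 - ty) * (1 - tz) * g(0, 0, 0) +
    tx * (1 - ty) * (1 - tz) * g(1, 0, 0) +
    (1 - tx) * ty * (1 - tz) * g(0, 1, 0) +
    (1 - tx) * (1 - ty) * tz * g(0, 0, 1) +
    tx * ty * (1 - tz) * g(1, 1, 0) +
    tx * (1 - ty) * tz * g(1, 0, 1) +
    (1 - tx) * ty * tz * g(0, 1, 1) +
    tx * ty * tz * g(1, 1, 1)
}

#' Compare two fields on common probe points
#'
#' @param a,b Numeric vectors (same length).
#' @param mask Optional logical/integer subset.
#' @return A tibble: `rel_l2` (symmetric, `2||a-b|| / (||a|| + ||b||)`),
#'   `linf` (max absolute difference), `bias` (mean of `a - b`).
#' @export
compare_fields <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (!length(a)) stop("empty comparison mask")
  stopifnot(length(a) == length(b))
  denom <- sqrt(sum(a^2)) + sqrt(sum(b^2))
  tibble::tibble(
    rel_l2 = if (denom > 0) 2 * sqrt(sum((a - b)^2)) / denom else 0,
    linf = max(abs(a - b)),
    bias = mean(a - b)
  )
}
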