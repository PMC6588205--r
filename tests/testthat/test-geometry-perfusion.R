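# Hull construction, paired-surface gradients, sphere packing and tissue
# perfusion.

test_that("the convex hull reproduces closed-form solids", {
  cube <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  hull <- compute_hull(cube)
  expect_equal(nrow(hull$vertices), 8L)
  expect_equal(hull$volume_cm3, 1 * tf_units$um_to_cm^3)
  expect_equal(hull$area_cm2, 6 * tf_units$um_to_cm^2)
  # a regular tetrahedron with edge a has volume a^3 / (6 sqrt(2))
  a <- 200
  tet <- a / sqrt(2) * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2)
  et <- sqrt(sum((tet[1, ] - tet[2, ])^2))
  hull_t <- compute_hull(tet)
  expect_equal(hull_t$volume_cm3, et^3 / (6 * sqrt(2)) * tf_units$um_to_cm^3,
               tolerance = 1e-12)
  # interior points never join the hull
  withp <- rbind(cube * 1000, c(500, 500, 500))
  expect_equal(nrow(compute_hull(withp)$vertices), 8L)
  expect_error(compute_hull(cube[c(1, 2, 3, 4), ] * c(1, 1, 0)), "degenerate|collinear")
})

test_that("subdivision multiplies face counts by four and keeps the volume", {
  cube <- as.matrix(expand.grid(x = c(0, 1000), y = c(0, 1000), z = c(0, 1000)))
  h0 <- compute_hull(cube, 0L)
  h1 <- compute_hull(cube, 1L)
  h2 <- compute_hull(cube, 2L)
  expect_equal(nrow(h1$faces), 4L * nrow(h0$faces))
  expect_equal(nrow(h2$faces), 16L * nrow(h0$faces))
  expect_equal(h1$volume_cm3, h0$volume_cm3)
  expect_equal(h2$area_cm2, h0$area_cm2)
})

test_that("hull volume is invariant under rigid-body motion", {
  set.seed(8)
  pts <- matrix(stats::rnorm(150), ncol = 3) * 300
  h0 <- compute_hull(pts)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  h1 <- compute_hull(pts %*% R + matrix(c(100, -50, 20), nrow(pts), 3, byrow = TRUE))
  expect_equal(h1$volume_cm3, h0$volume_cm3, tolerance = 1e-10)
})

test_that("membership and ray distances agree with the sphere geometry", {
  sph <- tumourflow:::fibonacci_sphere(400, radius = 500)
  hull <- compute_hull(sph, 1L)
  expect_true(all(in_hull(hull, rbind(c(0, 0, 0), c(100, -100, 50)))))
  expect_false(any(in_hull(hull, rbind(c(600, 0, 0), c(0, 0, -700)))))
  d <- hull_ray_distance(hull, tumourflow:::fibonacci_sphere(50))
  expect_true(all(d > 480 & d <= 500 + 1e-9))
  r <- normalised_radius(rbind(c(0, 0, 0), c(0, 0, 249), c(498, 0, 0)), hull)
  expect_lt(r[1], 1e-3)  # the hull centroid of a finite point set is near 0
  expect_equal(r[2], 249 / 500, tolerance = 0.02)
  expect_gt(r[3], 0.99)
})

test_that("paired-surface velocities carry the sign of the enclosed source", {
  cs <- reference_configuration("central_source_sphere")
  hull <- compute_hull(cs$hull_points, 1L)
  ip <- interstitial_params()
  src <- cs$sources
  src$q_cm3_s <- 1e-9
  vel_out <- paired_surface_velocities(hull, interstitial_field(src, ip))
  expect_true(all(vel_out$v_n_um_s < 0))  # source inside -> outflow everywhere
  src$q_cm3_s <- -1e-9
  vel_in <- paired_surface_velocities(hull, interstitial_field(src, ip))
  expect_true(all(vel_in$v_n_um_s > 0))
  expect_equal(vel_in$v_n_um_s, -vel_out$v_n_um_s)
  # a sourceless (uniform) field induces no surface flow
  src0 <- src
  src0$q_cm3_s <- 0
  vel0 <- paired_surface_velocities(hull, interstitial_field(src0, ip))
  expect_equal(max(abs(vel0$v_n_um_s)), 0)
})

test_that("packed spheres never overlap and respect the mesh spacing", {
  sph <- tumourflow:::fibonacci_sphere(300, radius = 400)
  hull <- compute_hull(sph, 1L)
  packing <- sphere_pack_surface(hull)
  expect_gt(nrow(packing), 100L)
  centres <- as.matrix(packing[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(centres))
  sep <- D - outer(packing$radius_um, packing$radius_um, "+")
  diag(sep) <- Inf
  expect_gte(min(sep), -1e-9)
  # total disc area cannot exceed the hull surface
  expect_lte(sum(pi * (packing$radius_um * tf_units$um_to_cm)^2), hull$area_cm2)
  expect_identical(packing, sphere_pack_surface(hull))
})

test_that("surface-sphere quadrature recovers the enclosed source flux", {
  cs <- reference_configuration("central_source_sphere")
  hull <- compute_hull(cs$hull_points, 2L)
  ip <- interstitial_params()
  src <- cs$sources
  src$q_cm3_s <- 1e-9
  fld <- interstitial_field(src, ip)
  vel <- paired_surface_velocities(hull, fld)
  packing <- sphere_pack_surface(hull)
  v_cm_min <- vel$v_n_um_s[packing$vertex] * 1e-4 * 60
  area <- pi * (packing$radius_um * 1e-4)^2
  w <- area * hull$area_cm2 / sum(area)  # discs as a normalised quadrature rule
  outflow_ml_min <- -sum(v_cm_min * w)
  q_ml_min <- 1e-9 * 60
  expect_lt(abs(outflow_ml_min - q_ml_min) / q_ml_min, 0.15)
})

test_that("total perfusion composes its components with the right units", {
  fx <- fx_tumour()
  cfx <- fx_coupled()
  perf <- total_perfusion(fx$flow, fx$hull, cfx$cp$field, fx$net)
  expect_gt(perf$vascular_ml_min, 0)
  expect_gte(perf$interstitial_ml_min, 0)
  expect_equal(perf$mass_g, fx$hull$volume_cm3)  # density 1 g/cm3
  expect_equal(perf$perfusion_ml_min_100g,
               100 * (perf$vascular_ml_min + perf$interstitial_ml_min) / perf$mass_g)
  # only inflow counts by default; the net option cannot exceed it
  net_mode <- total_perfusion(fx$flow, fx$hull, cfx$cp$field, fx$net, mode = "net")
  expect_lte(net_mode$perfusion_ml_min_100g, perf$perfusion_ml_min_100g)
  # a central source drives outflow only: zero interstitial inflow component
  cs <- reference_configuration("central_source_sphere")
  hull_s <- compute_hull(cs$hull_points, 1L)
  src <- cs$sources
  src$q_cm3_s <- 1e-9
  hp <- haemo_params()
  cond <- assemble_conductance(cs$network, hp)
  fl <- solve_poiseuille(cs$network, cond, stats::setNames(c(25.1, 24.9), 1:2))
  perf_c <- total_perfusion(fl, hull_s, interstitial_field(src, interstitial_params()),
                            cs$network)
  expect_equal(perf_c$interstitial_ml_min, 0)
})

test_that("doubling all boundary pressure drops doubles the vascular component", {
  # four-arm star with terminals at tetrahedron vertices: every terminal is
  # a surface boundary node of its own hull
  tet <- 300 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  arm <- sqrt(sum(tet[1, ]^2))
  net <- vascular_network(
    data.frame(id = 1:5, x = c(0, tet[, 1]), y = c(0, tet[, 2]), z = c(0, tet[, 3])),
    data.frame(id = 1:4, from = 1, to = 2:5, diameter = 12, length = arm)
  )
  hull <- compute_hull(node_coords(net))
  cond <- assemble_conductance(net, haemo_params())
  bc1 <- stats::setNames(c(36, 28, 28, 28), 2:5)
  sol1 <- solve_poiseuille(net, cond, bc1)
  p1 <- total_perfusion(sol1, hull, NULL, net)
  bc2 <- mean(bc1) + 2 * (bc1 - mean(bc1))
  sol2 <- solve_poiseuille(net, cond, bc2)
  p2 <- total_perfusion(sol2, hull, NULL, net)
  expect_gt(p1$vascular_ml_min, 0)
  expect_equal(p2$vascular_ml_min, 2 * p1$vascular_ml_min, tolerance = 1e-10)
})
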