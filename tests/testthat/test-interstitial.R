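# Regularized Green's kernels, source distribution, the Starling-coupled
# source system and field evaluation.

test_that("the regularized kernel takes its closed-form branch values", {
  expect_equal(greens_function(0, 1, 1), 3 / (8 * pi))
  expect_equal(greens_function(2, 1, 1), 1 / (8 * pi))
  expect_equal(greens_gradient(0, 1, 1), 0)
  expect_equal(greens_gradient(2, 1, 1), -1 / (16 * pi))
})

test_that("kernel and gradient are continuous at the source radius", {
  for (r0 in c(0.3, 1, 4.45)) {
    for (kap in c(1, 1.7e-7)) {
      eps <- r0 * 1e-9
      expect_equal(greens_function(r0 - eps, r0, kap),
                   greens_function(r0 + eps, r0, kap), tolerance = 1e-7)
      expect_equal(greens_function(r0, r0, kap), 1 / (4 * pi * kap * r0))
      expect_equal(greens_gradient(r0, r0, kap), -1 / (4 * pi * kap * r0^2))
      expect_equal(greens_gradient(r0 - eps, r0, kap),
                   greens_gradient(r0 + eps, r0, kap), tolerance = 1e-7)
    }
  }
})

test_that("sources partition segments at the requested spacing", {
  net <- vascular_network(
    data.frame(id = 1:3, x = c(0, 100, 110), y = 0, z = 0),
    data.frame(id = 1:2, from = 1:2, to = 2:3, diameter = 10, length = c(100, 10))
  )
  cond <- assemble_conductance(net, haemo_params())
  fl <- solve_poiseuille(net, cond, stats::setNames(c(30, 20), c(1L, 3L)))
  src <- distribute_sources(net, fl, 25)
  expect_equal(sum(src$segment == 1), 4L)       # ceiling(100/25)
  expect_equal(unique(src$l_um[src$segment == 1]), 25)
  expect_equal(sum(src$segment == 2), 1L)       # single midpoint source
  expect_equal(src$x[src$segment == 2], 105)
  expect_equal(sum(src$l_um), sum(net$segments$length))
  # vascular pressure interpolates linearly along the segment
  p1 <- fl$nodes$pressure_mmHg[1]; p2 <- fl$nodes$pressure_mmHg[2]
  expect_equal(src$p_b_mmHg[src$segment == 1],
               p1 + (c(1, 3, 5, 7) / 8) * (p2 - p1))
  expect_equal(src$r0_um, rep(5, 5))
})

test_that("the Starling right-hand side matches the parameter arithmetic", {
  one <- reference_configuration("one_source", p_b_mmHg = 25)
  sys <- assemble_source_system(one$sources, interstitial_params())
  expect_equal(sys$b, 25 - 0.82 * (20 - 15))  # = 20.9 mmHg
})

test_that("the wall-permeability term vanishes as L_p grows", {
  two <- reference_configuration("two_source_symmetric")
  ip_inf <- interstitial_params(L_p = 1e6)
  sys <- assemble_source_system(two$sources, ip_inf)
  # pure Green's matrix
  pos <- cbind(two$sources$x, two$sources$y, two$sources$z) * tf_units$um_to_cm
  r12 <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  G <- matrix(c(greens_function(0, 5e-4, ip_inf$kappa),
                greens_function(r12, 5e-4, ip_inf$kappa),
                greens_function(r12, 5e-4, ip_inf$kappa),
                greens_function(0, 5e-4, ip_inf$kappa)), 2, 2)
  expect_equal(sys$A, G, tolerance = 1e-10)
  expect_equal(sys$A, t(sys$A))  # symmetric for equal mirror sources
})

test_that("mirror-symmetric sources receive identical strengths", {
  two <- reference_configuration("two_source_symmetric")
  for (st in c("drop", "wall", "identify")) {
    src <- solve_source_strengths(
      assemble_source_system(two$sources, interstitial_params(self_term = st)))
    expect_equal(src$q_cm3_s[1], src$q_cm3_s[2], tolerance = 1e-12)
  }
})

test_that("an isolated source with large L_p inverts the 1x1 Green's system", {
  one <- reference_configuration("one_source", p_b_mmHg = 25)
  ip <- interstitial_params(L_p = 1e9)
  src <- solve_source_strengths(assemble_source_system(one$sources, ip))
  b <- 25 - 0.82 * 5
  expect_equal(src$q_cm3_s, b * 8 * pi * ip$kappa * 5e-4 / 3, tolerance = 1e-6)
})

test_that("field evaluation superposes the closed-form kernels", {
  one <- reference_configuration("one_source")
  ip <- interstitial_params(p_inf_mmHg = 3)
  src <- one$sources
  src$q_cm3_s <- 2e-9
  fld <- interstitial_field(src, ip)
  # no sources -> far-field everywhere
  empty <- interstitial_field(src[0, ], ip)
  expect_equal(evaluate_ifp(cbind(1:3, 0, 0), empty), rep(3, 3))
  # outside the source sphere: p = p_inf + q / (4 pi kappa r)
  r_um <- c(10, 50, 400)
  p <- evaluate_ifp(cbind(r_um, 0, 0), fld)
  expect_equal(p, 3 + 2e-9 / (4 * pi * ip$kappa * r_um * 1e-4))
  # two sources superpose pointwise
  two <- reference_configuration("two_source_symmetric")
  s2 <- two$sources
  s2$q_cm3_s <- c(1e-9, 3e-9)
  f2 <- interstitial_field(s2, ip)
  pts <- cbind(c(-20, 0, 35), c(5, 0, -10), 0)
  p_a <- evaluate_ifp(pts, interstitial_field(s2[1, ], ip))
  p_b <- evaluate_ifp(pts, interstitial_field(s2[2, ], ip))
  expect_equal(evaluate_ifp(pts, f2), p_a + p_b - 3)  # p_inf counted once
})

test_that("velocity is radial with conductivity-independent far field", {
  one <- reference_configuration("one_source")
  for (kap in c(1.7e-7, 5e-6)) {
    ip <- interstitial_params(kappa = kap)
    src <- one$sources
    src$q_cm3_s <- 2e-9
    fld <- interstitial_field(src, ip)
    pts <- cbind(c(50, 0), c(0, 80), 0)
    u <- evaluate_ifv(pts, fld)
    r_cm <- c(50, 80) * 1e-4
    u_expect <- 2e-9 / (4 * pi * r_cm^2) * tf_units$cm_s_to_um_s
    expect_equal(u[1, ], c(u_expect[1], 0, 0))
    expect_equal(u[2, ], c(0, u_expect[2], 0))
    expect_equal(evaluate_ifv(cbind(0, 0, 0), fld), matrix(0, 1, 3))
  }
})

test_that("flux through any enclosing sphere equals the source strength", {
  one <- reference_configuration("one_source")
  ip <- interstitial_params()
  src <- one$sources
  src$q_cm3_s <- 5e-10
  fld <- interstitial_field(src, ip)
  quad <- tumourflow:::fibonacci_sphere(2000)
  for (r_um in c(20, 150)) {
    u <- evaluate_ifv(quad * r_um, fld) / tf_units$cm_s_to_um_s  # cm/s
    flux <- mean(rowSums(u * quad)) * 4 * pi * (r_um * 1e-4)^2
    expect_equal(flux, 5e-10, tolerance = 1e-6)
  }
})

test_that("solved fields honour the Starling wall balance", {
  # p_b - K_i J_v,i - sigma dPi equals the IFP at the source, because the
  # linear system enforces exactly that identity
  fx <- fx_ten_sources()
  Jv <- transvascular_flux(fx$field)
  ps <- tumourflow:::resolve_source_params(fx$src, fx$ip)
  S <- 2 * pi * (fx$src$rv_um * 1e-4) * (fx$src$l_um * 1e-4)
  K <- 1 / (ps$L_p * S)
  lhs <- fx$src$p_b_mmHg - K * Jv$J_v_cm3_s -
    ps$sigma * (fx$ip$Pi_b_mmHg - fx$ip$Pi_v_mmHg)
  ifp_at_sources <- evaluate_ifp(cbind(fx$src$x, fx$src$y, fx$src$z), fx$field)
  expect_equal(lhs, ifp_at_sources, tolerance = 1e-8)
})

test_that("an isolated leaky source filters outward under wall closure", {
  one <- reference_configuration("one_source", p_b_mmHg = 25)
  ip <- interstitial_params(self_term = "wall")
  src <- solve_source_strengths(assemble_source_system(one$sources, ip))
  Jv <- transvascular_flux(interstitial_field(src, ip))
  expect_gt(Jv$J_v_cm3_s, 0)       # p_b above p_inf + sigma dPi drives filtration
  expect_gt(src$q_cm3_s, 0)
  # all-zero strengths give zero flux
  src0 <- src
  src0$q_cm3_s <- 0
  expect_equal(transvascular_flux(interstitial_field(src0, ip))$J_v_ul_min, 0)
})

test_that("the evaluated field is harmonic away from the sources", {
  fx <- fx_ten_sources()
  h <- 2
  centre <- c(55, 10, -12)  # outside every source sphere
  offs <- rbind(c(0, 0, 0), h * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  p <- evaluate_ifp(sweep(offs, 2L, centre, "+"), fx$field)
  lap <- (sum(p[-1]) - 6 * p[1]) / h^2
  expect_lt(abs(lap) / (abs(p[1]) / h^2), 1e-3)
})

test_that("zero wall conductance suppresses filtration entirely", {
  fx <- fx_tumour()
  src <- distribute_sources(fx$net, fx$flow, 120)
  ip0 <- interstitial_params(L_p = 0)
  cp <- couple(fx$net, fx$flow, src, ip0, conductance = fx$cond)
  expect_true(cp$converged)
  expect_equal(cp$iterations, 1L)
  expect_equal(max(abs(cp$sources$q_cm3_s)), 0)
  pts <- cbind(c(0, 200), c(0, -100), c(0, 50))
  expect_equal(evaluate_ifp(pts, cp$field), rep(ip0$p_inf_mmHg, 2))
})
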