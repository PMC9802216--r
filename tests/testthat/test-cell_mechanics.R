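test_that("ellipse coefficients match the worked examples and invert exactly", {
  co <- coeffs_from_geometry(1, 1, 0.7)
  expect_equal(unname(unlist(co)), c(1, 0, 1))
  co <- coeffs_from_geometry(2, 1, 0)
  expect_equal(unname(unlist(co)), c(0.25, 0, 1))
  co <- coeffs_from_geometry(2, 1, pi / 2)
  expect_equal(unname(unlist(co)), c(1, 0, 0.25), tolerance = 1e-14)

  g <- geometry_from_coeffs(0.25, 0, 1)
  expect_equal(c(g$a1_hat, g$a2_hat, g$theta), c(2, 1, 0))
  g <- geometry_from_coeffs(1, 0, 1)
  expect_equal(g$theta, 0)       # tie-break for circles
  expect_true(g$is_circular)

  expect_error(geometry_from_coeffs(1, 3, 1), "invalid ellipse")
  expect_error(coeffs_from_geometry(-1, 1, 0), "positive")
  expect_error(coeffs_from_geometry(1, 2, 0), "a1_hat")
})

test_that("geometry round trip is the identity over random valid states", {
  set.seed(11)
  n <- 1000
  a1 <- runif(n, 0.31, 3.9)
  a2 <- runif(n, 0.3, a1)
  th <- runif(n, 0, pi)
  co <- coeffs_from_geometry(a1, a2, th)
  g <- geometry_from_coeffs(co$h, co$k, co$l)
  expect_equal(g$a1_hat, a1, tolerance = 1e-12)
  expect_equal(g$a2_hat, a2, tolerance = 1e-12)
  circ <- g$is_circular
  dth <- abs((g$theta - th + pi / 2) %% pi - pi / 2)
  expect_lt(max(dth[!circ]), 1e-9)
  # area identity A_hat * sqrt(h l - k^2/4) = 1
  expect_equal(g$a1_hat * g$a2_hat * sqrt(co$h * co$l - co$k^2 / 4),
               rep(1, n), tolerance = 1e-12)
})

test_that("area and aspect ratio derive from the axes", {
  m <- microstate(1 / 0.96^2, 0, 1 / 0.96^2)
  expect_equal(unname(area_aspect(m)), c(0.9216, 1))
  co <- coeffs_from_geometry(2, 0.5, 1.1)
  m <- microstate(co$h, co$k, co$l)
  expect_equal(unname(area_aspect(m)), c(1, 4), tolerance = 1e-12)
})

test_that("substrate strain protocol follows the sinusoid and biaxiality", {
  l <- cyclic_load(eps_amp = 0.1, f = 1, r = 0.5, eps_mean = 0.02)
  s0 <- substrate_strain(0, l)
  expect_equal(s0$eps1, 0.02)
  expect_equal(s0$deps1, pi * 1 * 0.1)
  expect_equal(s0$eps2, -0.5 * s0$eps1)
  sq <- substrate_strain(l$T_p / 4, l)
  expect_equal(sq$eps1, 0.02 + 0.05)
  expect_equal(sq$deps1, 0, tolerance = 1e-15)
  l0 <- cyclic_load(eps_amp = 0.1, f = 1, r = 0)
  tt <- seq(0, 1, by = 0.1)
  expect_true(all(substrate_strain(tt, l0)$eps2 == 0))
})

test_that("fiber kinematics: strain from morphology, rate from the substrate", {
  m <- microstate(1, 0, 1)
  k <- fiber_kinematics(m, load_1hz, 0.3, phi_grid(36))
  expect_equal(k$eps_nom, rep(0, 36))

  # elongated cell at 90 deg: major-axis fibers are perpendicular to the
  # uniaxial strain and stay isometric at all times
  co <- coeffs_from_geometry(2, 1, pi / 2)
  m90 <- microstate(co$h, co$k, co$l)
  for (t in seq(0, 0.9, by = 0.11))
    expect_equal(fiber_kinematics(m90, load_1hz, t, 0)$eps_rate, 0,
                 tolerance = 1e-14)

  # at 0 deg the same fiber feels the full contraction rate at T_p/2
  co <- coeffs_from_geometry(2, 1, 0)
  m0 <- microstate(co$h, co$k, co$l)
  expect_equal(fiber_kinematics(m0, load_1hz, 0.5, 0)$eps_rate,
               -pi * 1 * 0.1, tolerance = 1e-12)
})

test_that("passive energy vanishes only in the undeformed state", {
  cp <- cp_default
  expect_equal(passive_energy(microstate(1, 0, 1), cp), 0)
  co <- coeffs_from_geometry(1, 1, 1.2) # rotation of the circle
  expect_equal(passive_energy(microstate(co$h, co$k, co$l), cp), 0)
  # J = 1 shear: W = (mu/2)(lam1^2 + lam2^2 - 2) per unit area
  co <- coeffs_from_geometry(2, 0.5, 0)
  H <- passive_energy(microstate(co$h, co$k, co$l), cp)
  mu_eff <- pi * ((cp$R0^2 - cp$R_N^2) * cp$mu_cyto + cp$R_N^2 * cp$mu_nuc)
  expect_equal(H, (mu_eff / 2) * (4.25 - 2), tolerance = 1e-12)
  expect_gt(H, 0)
})

test_that("cycle-averaged energy is periodic-start invariant and converges", {
  co <- coeffs_from_geometry(1.8, 0.8, pi / 3)
  m <- microstate(co$h, co$k, co$l)
  H_a <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default,
                               n_time = 256, t_I = 0)
  H_b <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default,
                               n_time = 256, t_I = 0.37 * load_1hz$T_p)
  # the clipped Hill factor has kinks, so periodic quadrature converges
  # algebraically rather than spectrally
  expect_lt(abs(H_a - H_b), 1e-4)
  H_a2 <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default,
                                n_time = 1024, t_I = 0)
  H_b2 <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default,
                                n_time = 1024, t_I = 0.37 * load_1hz$T_p)
  expect_lt(abs(H_a2 - H_b2), abs(H_a - H_b)) # shift error shrinks with n
  H64 <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default, n_time = 64)
  H128 <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default, n_time = 128)
  expect_lt(abs(H128 - H64), 2e-3)
  H256 <- cycle_averaged_energy(m, load_1hz, sfp_default, cp_default, n_time = 256)
  expect_lt(abs(H256 - H128), abs(H128 - H64)) # quadrature refinement
})

test_that("static loads reduce to a single evaluation", {
  co <- coeffs_from_geometry(1.5, 0.9, 0.4)
  m <- microstate(co$h, co$k, co$l)
  H_f0 <- cycle_averaged_energy(m, load_static, sfp_default, cp_default)
  H_amp0 <- cycle_averaged_energy(m, cyclic_load(eps_amp = 0, f = 1),
                                  sfp_default, cp_default)
  expect_equal(H_f0, H_amp0, tolerance = 1e-12)
  expect_equal(H_f0, cell_energy_instant(m, load_static, 0, sfp_default,
                                         cp_default) / abs(cp_default$H_s),
               tolerance = 1e-12)
})

test_that("energy respects the axis-relabeling and static rotation symmetries", {
  sfp <- sfp_default; cp <- cp_default
  co_a <- coeffs_from_geometry(1.9, 0.7, 0.5)
  co_b <- coeffs_from_geometry(1.9, 0.7, 0.5 + pi) # theta + pi identical state
  expect_equal(hhat_cells(co_a$h, co_a$k, co_a$l, load_1hz, sfp, cp, n_time = 16),
               hhat_cells(co_b$h, co_b$k, co_b$l, load_1hz, sfp, cp, n_time = 16),
               tolerance = 1e-12)
  # under f = 0 the energy cannot depend on orientation
  th <- seq(0, pi, length.out = 13)
  co <- coeffs_from_geometry(rep(1.9, 13), rep(0.7, 13), th)
  H <- hhat_cells(co$h, co$k, co$l, load_static, sfp, cp)
  expect_lt(max(H) - min(H), 1e-8)
  # under r-type loading H(theta) = H(pi - theta)
  co_p <- coeffs_from_geometry(1.9, 0.7, 0.3)
  co_m <- coeffs_from_geometry(1.9, 0.7, pi - 0.3)
  expect_equal(hhat_cells(co_p$h, co_p$k, co_p$l, load_1hz, sfp, cp, n_time = 32),
               hhat_cells(co_m$h, co_m$k, co_m$l, load_1hz, sfp, cp, n_time = 32),
               tolerance = 1e-10)
})

test_that("an elongated cell along the strain axis pays a cyclic energy cost", {
  co0 <- coeffs_from_geometry(1.9, 0.7, 0)
  co90 <- coeffs_from_geometry(1.9, 0.7, pi / 2)
  H0 <- hhat_cells(co0$h, co0$k, co0$l, load_1hz, sfp_default, cp_default)
  H90 <- hhat_cells(co90$h, co90$k, co90$l, load_1hz, sfp_default, cp_default)
  expect_gt(H0, H90)
})

test_that("suspension state matches the stated geometry and sign", {
  expect_equal(cp_default$suspension_radius_factor^2, 0.9216)
  expect_lt(cp_default$H_s, 0)
  # with factor 1 the passive contribution vanishes: pure cytoskeletal term
  cp1 <- cell_params(suspension_radius_factor = 1 - 1e-12)
  m1 <- microstate(1, 0, 1)
  expect_equal(suspension_energy(sfp_default, cp1),
               suspension_energy(sfp_default, cp1) - passive_energy(m1, cp1))
})
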