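test_that("phase-space sampler is reproducible and respects the constraints", {
  s1 <- sample_phase_space(1000, seed = 5)
  s2 <- sample_phase_space(1000, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(4 * s1$h * s1$l - s1$k^2 > 0))
  expect_true(all(s1$a1_hat <= 4 & s1$a2_hat >= 0.3))
  expect_true(all(s1$a1_hat >= s1$a2_hat))
  expect_error(sample_phase_space(10, seed = 1, bounds = list(
    h = c(-2, -1), k = c(0, 0.1), l = c(-2, -1))), "bounds")
})

test_that("sampler acceptance matches an independent volume estimate", {
  s <- sample_phase_space(20000, seed = 5)
  p_hat <- attr(s, "acceptance")
  # independent brute-force estimate of the valid-region volume fraction
  # using eigen-decomposition rather than the sampler's closed forms
  set.seed(99)
  lo <- 1 / 16; hi <- 1 / 0.09
  n <- 20000
  h <- runif(n, lo, hi); k <- runif(n, -(hi - lo), hi - lo); l <- runif(n, lo, hi)
  ok <- vapply(seq_len(n), function(i) {
    ev <- eigen(matrix(c(h[i], k[i] / 2, k[i] / 2, l[i]), 2), symmetric = TRUE,
                only.values = TRUE)$values
    all(ev > 0) && 1 / sqrt(min(ev)) <= 4 && 1 / sqrt(max(ev)) >= 0.3
  }, TRUE)
  p_ref <- mean(ok)
  se <- sqrt(p_ref * (1 - p_ref) / n + p_hat * (1 - p_hat) / 20000)
  expect_lt(abs(p_hat - p_ref), 3 * se + 1e-12)
})

test_that("Boltzmann weights reproduce the two-state closed form", {
  fx <- make_fixtures("two_state_ensemble")
  w <- equilibrium_weights(fx$energies, fx$beta_hat_exact)
  expect_equal(w, fx$weights_exact, tolerance = 1e-12)
  expect_equal(equilibrium_weights(c(3, 3, 3), 7), rep(1 / 3, 3))
  expect_equal(equilibrium_weights(c(-5, 2, 40), 0), rep(1 / 3, 3))
  # overflow safety
  w <- equilibrium_weights(c(-2000, -1000), 5)
  expect_equal(sum(w), 1)
  expect_false(any(is.nan(w)))
})

test_that("homeostatic constraint solve is exact on the two-state system", {
  fx <- make_fixtures("two_state_ensemble")
  b <- solve_beta(fx$energies, target = fx$target)
  expect_equal(b, 2 * log(1.5), tolerance = 1e-9)
  expect_error(solve_beta(c(-0.5, -0.4), target = -1), "infeasible")
  expect_error(solve_beta(c(-1, -1), target = -1), "constraint")
})

test_that("the constrained mean energy is strictly decreasing in beta", {
  set.seed(3)
  for (i in 1:10) {
    E <- rnorm(50)
    bs <- seq(-3, 3, length.out = 25)
    mE <- vapply(bs, function(b) sum(E * equilibrium_weights(E, b)), 0)
    expect_true(all(diff(mE) < 0))
  }
})

test_that("a solved ensemble satisfies the homeostatic residual and weight sum", {
  ens <- small_ensemble(load_static)
  w <- ens$samples$weight
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(abs(sum(w * ens$samples$H_hat) - sign(ens$H_s)), 1e-10)
  expect_gt(ens$beta_hat, 0)
})

test_that("orientation is unbiased without load and perpendicular under load", {
  ens0 <- small_ensemble(load_static, n = 4000)
  d0 <- morphology_densities(ens0, bins_theta = 6)$theta
  # no preferential orientation: each of 6 bins near 1/pi within noise
  ess <- 1 / sum(ens0$samples$weight^2)
  expect_lt(max(abs(d0$density - 1 / pi)), 3 * sqrt(6 / ess) / pi + 0.05)
  ens1 <- small_ensemble(load_1hz, n = 4000)
  d1 <- morphology_densities(ens1, bins_theta = 18)$theta
  expect_equal(d1$mid[which.max(d1$density)], pi / 2, tolerance = pi / 18)
})

test_that("degenerate weights give a delta-like histogram", {
  ens <- small_ensemble(load_static, n = 500)
  ens$samples$weight <- c(1, rep(0, nrow(ens$samples) - 1))
  d <- morphology_densities(ens, bins_shape = 25)$A_hat
  expect_equal(sum(d$density > 0), 1)
})

test_that("angular densities validate and the CV has its analytic values", {
  g <- phi_grid(360)
  expect_equal(circular_variance(angular_density(g, rep(1 / pi, 360))), 1,
               tolerance = 1e-12)
  delta <- c(360 / pi, rep(0, 359))
  expect_equal(circular_variance(angular_density(g, delta)), 0,
               tolerance = 1e-3) # one-bin delta: alignment up to bin width
  cosd <- (2 / pi) * cos(g)^2
  expect_equal(circular_variance(angular_density(g, cosd)), 0.5,
               tolerance = 1e-6)
  expect_error(angular_density(g, rep(1, 360)), "integrate")
  expect_error(circular_variance(list(grid = g, density = rep(2 / pi, 360))),
               "integrate")
})

test_that("global and cell-frame SF distributions coincide for circular cells", {
  phi <- phi_grid(36)
  n <- 40
  ybar <- matrix(rep(0.2 + 0.1 * cos(2 * phi), each = n), n, 36)
  fake <- structure(list(
    samples = data.frame(theta = rep(0, n), weight = rep(1 / n, n)),
    ybar = ybar, phi_grid = phi, H_s = -1), class = "ensemble_result")
  d <- sf_global_distribution(fake)
  expect_equal(d$xi_hat$density, d$rho_hat$density, tolerance = 1e-12)
  # and a rigid rotation of every cell shifts xi but not rho
  fake$samples$theta <- rep(pi / 4, n)
  d2 <- sf_global_distribution(fake)
  expect_equal(d2$rho_hat$density, d$rho_hat$density, tolerance = 1e-12)
  expect_equal(which.max(d2$xi_hat$density),
               (which.max(d$xi_hat$density) + 9 - 1) %% 36 + 1)
})

test_that("the static landscape is orientation independent", {
  gr <- seq(0.6, 2.6, length.out = 9)
  L0 <- free_energy_landscape(0, gr, gr, load_static, sfp_default, cp_default)
  L37 <- free_energy_landscape(37 * pi / 180, gr, gr, load_static,
                               sfp_default, cp_default)
  expect_equal(L0$H_hat, L37$H_hat, tolerance = 1e-10)
  expect_equal(L0$argmin, L37$argmin)
})
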