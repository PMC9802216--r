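#' Deterministic toy fixtures for testing and demonstration
#'
#' Small analytically tractable objects used by the test suite:
#' \describe{
#'   \item{`two_state_ensemble`}{the two-level system with normalized
#'     energies `(-1, -0.5)`; for the homeostatic target `-0.8` the exact
#'     solution is `beta_hat = 2 log(1.5)` with weights `(0.6, 0.4)`.}
#'   \item{`quadratic_landscape`}{a separable quadratic energy
#'     `H_hat = sum a_i (r_i - r0_i)^2` whose Langevin stationary law is a
#'     product Gaussian with variances `1/(2 beta_hat a_i)`
#'     (Ornstein-Uhlenbeck).}
#'   \item{`synthetic_rotation_paths`}{scripted trajectories with known
#'     accumulated rotation: pure rotation 0 to 90 degrees at constant
#'     shape, and a pure strain-mode axis swap with no rotation.}
#'   \item{`isotropic_sf_state`}{the zero-exponent stress-fiber state with
#'     `N_u = 1/2` and `eta_hat = 1/(2 pi)` on the angular grid.}
#' }
#'
#' @param kind One of the fixture names above.
#' @param seed Integer seed for any randomized pieces.
#' @return A list whose contents depend on `kind`; every fixture carries
#'   the analytic reference values it was built from.
#' @export
make_fixtures <- function(kind, seed = 1) {
  switch(kind,
    two_state_ensemble = list(
      energies = c(-1, -0.5),
      target = -0.8,
      beta_hat_exact = 2 * log(1.5),
      weights_exact = c(0.6, 0.4)
    ),
    quadratic_landscape = {
      a <- c(1, 2, 0.5)
      r0 <- c(1.2, 0, 1.2)
      list(
        a = a, r0 = r0,
        energy_fn = function(h, k, l)
          a[1] * (h - r0[1])^2 + a[2] * (k - r0[2])^2 + a[3] * (l - r0[3])^2,
        grad_fn = function(r) {
          g <- sweep(r, 2, r0, `-`)
          sweep(g, 2, 2 * a, `*`)
        },
        stationary_var = function(beta_hat) 1 / (2 * beta_hat * a)
      )
    },
    synthetic_rotation_paths = {
      n_steps <- 200L
      a1 <- 2; a2 <- 1
      t01 <- seq(0, 1, length.out = n_steps)
      rot <- coeffs_from_geometry(rep(a1, n_steps), rep(a2, n_steps),
                                  t01 * pi / 2)
      # strain mode: axes exchange through a circle, orientation fixed
      ax1 <- a1 + t01 * (a2 - a1)
      ax2 <- a2 + t01 * (a1 - a2)
      swap <- ax1 < ax2
      strn <- coeffs_from_geometry(pmax(ax1, ax2), pmin(ax1, ax2),
                                   ifelse(swap, pi / 2, 0))
      list(rotation = cbind(rot$h, rot$k, rot$l),
           strain = cbind(strn$h, strn$k, strn$l),
           theta_r_rotation = pi / 2,
           theta_r_strain = 0)
    },
    isotropic_sf_state = {
      p <- sf_params(sigma_max = 1, mu_b0 = 1, mu_u0 = 0, omega = 1, kT = 1,
                     eps_ss = 0)
      # chi = 0 requires omega*sigma + mu_u0 - mu_b0 = 0 at n_hat = 1
      s <- sf_steady_state(rep(0, p$n_angular), rep(0, p$n_angular), p)
      list(params = p, state = s, N_u_exact = 0.5,
           eta_exact = 1 / (2 * pi))
    },
    stop("unknown fixture kind: ", kind)
  )
}

#' Replay a scripted coefficient path through the rotation tracker
#'
#' Applies the same material-axis tracking rule as the Langevin engine to
#' an explicit sequence of `(h, k, l)` states and returns the accumulated
#' rotation. Used to validate the tracker on paths with known rotation,
#' including paths that cross aspect ratio 1 (axis relabeling).
#'
#' @param states An `n x 3` matrix of coefficient rows along the path.
#' @return List with `theta_r` (per step, accumulated) and `theta_r_aux`
#'   (`theta_r` folded into `[0, pi)`).
#' @export
track_rotation <- function(states) {
  stopifnot(is.matrix(states), ncol(states) == 3)
  pa <- principal_angle(states[, 1], states[, 2], states[, 3])
  psi <- pa[1]
  theta_r <- numeric(nrow(states))
  for (i in 2:nrow(states)) {
    d1 <- wrap_half(pa[i] - psi)
    d2 <- wrap_half(pa[i] + pi / 2 - psi)
    d <- if (abs(d1) <= abs(d2)) d1 else d2
    psi <- psi + d
    theta_r[i] <- theta_r[i - 1] + d
  }
  list(theta_r = theta_r, theta_r_aux = theta_r %% pi)
}
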