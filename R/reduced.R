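#' Fixed-circular-cell stress-fiber distribution
#'
#' The reduced model used to isolate stress-fiber remodeling from cell
#' morphology: the cell is held as a circle of radius `R0`, so the global
#' angle `delta` and the cell-frame angle coincide and the ensemble average
#' collapses to a single SF-model evaluation. The cycle-averaged
#' `eta_hat * n_hat` over one loading period, normalized, gives
#' `xi_hat_circ(delta)` and its circular variance.
#'
#' @param load A [cyclic_load()] object.
#' @param sfp An [sf_params()] object.
#' @param cp A [cell_params()] object (sets the circle radius `R0`).
#' @param n_time Quadrature instants per cycle.
#' @return A list with `xi_hat` (an `"angular_density"` on `delta`) and
#'   `CV` (scalar circular variance).
#' @examples
#' circular_cell_distribution(cyclic_load(f = 0), sf_params(), cell_params())$CV
#' @export
circular_cell_distribution <- function(load, sfp, cp, n_time = 64) {
  stopifnot(inherits(load, "cyclic_load"))
  m <- microstate(1, 0, 1) # circle of radius R0, theta = 0 by tie-break
  res <- hhat_cells(m$h, m$k, m$l, load, sfp, cp, n_time = n_time,
                    normalize = FALSE, return_sf = TRUE)
  y <- as.numeric(res$ybar)
  dgrid <- res$phi_grid
  dens <- y / (sum(y) * pi / length(y))
  d <- angular_density(dgrid, dens)
  list(xi_hat = d, CV = circular_variance(d))
}

#' Cycle-averaged free energy of the rod model
#'
#' One-dimensional (rod-like) reduction of the cell: the microstate is the
#' rod stretch `lam` and orientation `theta`. The whole SF population lies
#' along the rod axis, at nominal strain `lam - 1` and strain rate equal to
#' the substrate rate resolved at `theta`; the passive energy is the convex
#' 1D stretch energy `(mu_rod/2)(lam^2 + 2/lam - 3)`, zero at `lam = 1`.
#' The energy is normalized by the rod suspension value `|H_s_rod|`
#' (the rod at the suspension stretch, no imposed rate).
#'
#' @param lam Rod stretch (> 0), vectorized.
#' @param theta Rod orientation (rad), vectorized (recycled against `lam`).
#' @param load,sfp,cp Model objects (`mu_rod` is taken as
#'   `pi * R0^2 * mu_cyto`, the areal shear stiffness of the full model).
#' @param n_time Quadrature instants per cycle.
#' @param normalize Normalize by `|H_s_rod|`?
#' @return Numeric vector of normalized cycle-averaged rod energies.
#' @export
rod_energy <- function(lam, theta, load, sfp, cp, n_time = 64,
                       normalize = TRUE) {
  stopifnot(inherits(load, "cyclic_load"))
  if (any(lam <= 0)) stop("rod stretch must be positive")
  nlam <- max(length(lam), length(theta))
  lam <- rep_len(lam, nlam)
  theta <- rep_len(theta, nlam)
  H <- rod_energy_raw(lam, theta, load, sfp, cp, n_time)
  if (!normalize) return(H)
  H / abs(rod_suspension_energy(sfp, cp, n_time))
}

# suspended rod: reduced isometric stress, as in the full model
rod_suspension_energy <- function(sfp, cp, n_time) {
  sfp_susp <- sfp
  sfp_susp$sigma_max <- max(1e-300, cp$suspension_stress_factor * sfp$sigma_max)
  rod_energy_raw(cp$suspension_radius_factor, 0,
                 cyclic_load(eps_amp = 0, f = 0), sfp_susp, cp, n_time)
}

rod_energy_raw <- function(lam, theta, load, sfp, cp, n_time) {
  n_hat <- (lam) / (1 + sfp$eps_ss) # nominal strain lam - 1
  alpha <- sfp$omega * sfp$sigma_max / sfp$kT
  dmu <- (sfp$mu_u0 - sfp$mu_b0) / sfp$kT
  static <- load$f == 0 || load$eps_amp == 0
  times <- if (static) 0 else (seq_len(n_time) - 1) * load$T_p / n_time
  cd2 <- cos(theta)^2
  rate_dir <- cd2 - load$r * (1 - cd2)
  # slow remodeling: the rod's SF population sees the cycle-averaged stress
  fvbar <- 0
  for (t in times) {
    deps1 <- (load$eps_amp / 2) * 2 * pi * load$f * cos(2 * pi * load$f * t)
    fvbar <- fvbar +
      pmin(1, pmax(0, 1 + sfp$k_v * (deps1 * rate_dir) / sfp$eps_rate_0))
  }
  fvbar <- fvbar / length(times)
  n_eff <- n_hat * fvbar # unit count remodels with sustained tension
  chi <- n_eff * (alpha * fvbar + dmu)
  I <- exp(chi) * n_eff
  N_u <- 1 / (1 + I)
  y <- N_u * I # bound fraction, all at one orientation
  ylogy <- ifelse(y > 0, y * log(y), 0)
  H <- sfp$n_T * (sfp$mu_ref + sfp$kT *
    (y * n_eff * (sfp$mu_b0 / sfp$kT - alpha * fvbar) + N_u * sfp$mu_u0 / sfp$kT +
       N_u * log(N_u) + ylogy))
  mu_rod <- pi * cp$R0^2 * cp$mu_cyto
  H + (mu_rod / 2) * (lam^2 + 2 / lam - 3)
}

#' Orientation distribution of the rod-model ensemble
#'
#' Applies the homeostatic-ensemble machinery over the rod phase space
#' `(lam, theta)` on a uniform grid, solves the homeostatic constraint for
#' `beta_hat`, and returns the marginal orientation density `p(theta)` and
#' its modes. For biaxiality `r > 0` the density develops modes at the
#' orientations of vanishing cyclic strain rate,
#' `theta = atan(1/sqrt(r))` and `pi - atan(1/sqrt(r))`; for `r = 0` a
#' single mode at 90 degrees.
#'
#' @param load,sfp,cp Model objects.
#' @param n_lam,n_theta Grid resolution over stretch and orientation.
#' @param lam_range Range of rod stretches sampled.
#' @param n_time Quadrature instants per cycle.
#' @return A list with `p_theta` (data frame `theta`, `density`), `modes`
#'   (orientations of local maxima, rad), `beta_hat`.
#' @export
rod_orientation_density <- function(load, sfp, cp, n_lam = 60, n_theta = 72,
                                    lam_range = c(0.3, 4), n_time = 64) {
  lam <- seq(lam_range[1], lam_range[2], length.out = n_lam)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  gr <- expand.grid(lam = lam, theta = th)
  H <- rod_energy(gr$lam, gr$theta, load, sfp, cp, n_time = n_time)
  beta_hat <- solve_beta(H, target = sign(rod_suspension_energy(sfp, cp, n_time)))
  w <- equilibrium_weights(H, beta_hat)
  pw <- vapply(seq_len(n_theta),
               function(j) sum(w[gr$theta == th[j]]), 0)
  dens <- pw / (sum(pw) * pi / n_theta)
  # local maxima on the periodic grid
  up <- dens > c(dens[n_theta], dens[-n_theta])
  dn <- dens >= c(dens[-1], dens[1])
  modes <- th[up & dn & dens > 1.05 / pi] # maxima clearly above isotropy
  list(p_theta = data.frame(theta = th, density = dens),
       modes = modes, beta_hat = beta_hat)
}
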