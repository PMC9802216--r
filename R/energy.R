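#' Passive elastic energy of a microstate
#'
#' Both cytoplasm and nucleus deform with the uniform principal stretches
#' `(lambda1, lambda2) = (a1_hat, a2_hat)` of the ellipse. Each region
#' contributes its reference area times a 2D compressible neo-Hookean
#' strain-energy density
#' \deqn{W = \frac{\mu}{2}\Big(\frac{\lambda_1^2+\lambda_2^2}{J} - 2\Big)
#'         + \frac{\kappa}{2}(J-1)^2,\qquad J = \lambda_1\lambda_2,}
#' which vanishes only in the undeformed state and is invariant to rigid
#' rotation.
#'
#' @param m A `"microstate"` object.
#' @param p A [cell_params()] object.
#' @return Scalar passive energy, >= 0.
#' @export
passive_energy <- function(m, p) {
  stopifnot(inherits(m, "microstate"), inherits(p, "cell_params"))
  passive_energy_ab(m$a1_hat, m$a2_hat, p)
}

passive_energy_ab <- function(a1, a2, p) {
  J <- a1 * a2
  dev <- (a1^2 + a2^2) / J - 2
  W_c <- (p$mu_cyto / 2) * dev + (p$kappa_cyto / 2) * (J - 1)^2
  W_n <- (p$mu_nuc / 2) * dev + (p$kappa_nuc / 2) * (J - 1)^2
  A_cyto <- pi * (p$R0^2 - p$R_N^2)
  A_nuc <- pi * p$R_N^2
  A_cyto * W_c + A_nuc * W_n
}

#' Instantaneous cell free energy
#'
#' `H_cell(t) = H_cyto(t) + H_passive`, where the cytoskeletal part is the
#' steady-state stress-fiber free energy at the instantaneous strain and
#' strain-rate maps of the microstate under the imposed load.
#'
#' @param m A `"microstate"` object.
#' @param load A [cyclic_load()] object.
#' @param t Time (s, scalar).
#' @param sfp An [sf_params()] object.
#' @param cp A [cell_params()] object.
#' @return Scalar energy.
#' @export
cell_energy_instant <- function(m, load, t, sfp, cp) {
  phi <- phi_grid(sfp$n_angular)
  kin <- fiber_kinematics(m, load, t, phi)
  s <- sf_steady_state(kin$eps_nom, kin$eps_rate, sfp)
  cyto_free_energy(s, sfp) + passive_energy(m, cp)
}

#' Cycle-averaged normalized cell free energy
#'
#' Time-averages `H_cell(t)` over one loading period by the trapezoidal rule
#' on `n_time` equispaced instants (with periodic wrap, so the average is
#' independent of the arbitrary starting time `t_I`), then normalizes by
#' `|H_s|`:
#' \deqn{\hat H = \frac{1}{T_p |H_s|}\int_{t_I}^{t_I+T_p} H_{cell}(t)\,dt.}
#' For a static substrate (`f = 0` or zero amplitude) a single evaluation is
#' performed.
#'
#' @param m A `"microstate"` object.
#' @param load A [cyclic_load()] object.
#' @param sfp An [sf_params()] object.
#' @param cp A [cell_params()] object; if its `H_s` field is unset the
#'   suspension energy is computed on the fly.
#' @param n_time Number of quadrature instants per cycle (>= 8).
#' @param t_I Starting time of the averaging window (s).
#' @param normalize If `FALSE`, return the raw cycle-averaged energy
#'   instead of `H / |H_s|`.
#' @return Scalar `H_hat` (or raw energy).
#' @export
cycle_averaged_energy <- function(m, load, sfp, cp, n_time = 64, t_I = 0,
                                  normalize = TRUE) {
  stopifnot(inherits(m, "microstate"))
  if (n_time < 8) stop("n_time must be >= 8")
  H <- hhat_cells(m$h, m$k, m$l, load, sfp, cp, n_time = n_time, t_I = t_I,
                  normalize = normalize)
  as.numeric(H)
}

#' Free energy of the cell in suspension
#'
#' The suspended (unadhered) cell is a circle of radius
#' `suspension_radius_factor * R0` (so its normalized area is the factor
#' squared, 0.9216 by default) with no imposed strain rate. Because an
#' unadhered cell has no substrate to pull against, its stress fibers are
#' unloaded: the Hill stress is zero and only the rate-independent part of
#' the binding drive acts. Its free energy `H_s` is the homeostatic
#' target: the equilibrium ensemble is constrained to satisfy
#' `<H_cell> = H_s`. Under the calibrated defaults `H_s < 0`.
#'
#' @param sfp An [sf_params()] object.
#' @param cp A [cell_params()] object.
#' @return Scalar `H_s`.
#' @export
suspension_energy <- function(sfp, cp) {
  stopifnot(inherits(sfp, "sf_params"), inherits(cp, "cell_params"))
  a <- cp$suspension_radius_factor
  m <- microstate(1 / a^2, 0, 1 / a^2)
  sfp_susp <- sfp
  # without a substrate the SFs react only against the cell's own cortex,
  # sustaining a reduced isometric stress
  sfp_susp$sigma_max <- max(1e-300, cp$suspension_stress_factor * sfp$sigma_max)
  cell_energy_instant(m, cyclic_load(eps_amp = 0, f = 0), 0, sfp_susp, cp)
}

#' Attach the suspension energy to a parameter set
#'
#' Convenience helper: computes [suspension_energy()] once and caches it in
#' the `H_s` field of the cell parameters.
#'
#' @inheritParams suspension_energy
#' @return The `cell_params` object with `H_s` filled in.
#' @export
with_suspension_energy <- function(sfp, cp) {
  if (is.null(cp$H_s)) cp$H_s <- suspension_energy(sfp, cp)
  cp
}

# ---------------------------------------------------------------------------
# Batch evaluation of the cycle-averaged normalized free energy.
#
# This is the computational core shared by the ensemble sampler, the
# landscape scans, and the Langevin energy grid. All quantities are
# vectorized over microstates: matrices are [n_states x n_angular].
#
# For each state the fiber strain map (hence n_hat) is time-independent
# (set by the morphology); only the Hill factor varies within the cycle
# through the substrate strain rate resolved at the fiber's global angle.

# Returns H_hat vector; with return_sf = TRUE also the cycle-averaged
# eta_hat * n_hat matrix [n x n_angular] used for the SF order statistics.
hhat_cells <- function(h, k, l, load, sfp, cp, n_time = 64, t_I = 0,
                       normalize = TRUE, return_sf = FALSE,
                       chunk = 20000L) {
  stopifnot(inherits(load, "cyclic_load"), inherits(sfp, "sf_params"),
            inherits(cp, "cell_params"))
  n <- length(h)
  stopifnot(length(k) == n, length(l) == n)
  Hs_abs <- 1
  if (normalize) {
    cp <- with_suspension_energy(sfp, cp)
    Hs_abs <- abs(cp$H_s)
  }
  H <- numeric(n)
  ybar <- if (return_sf) matrix(0, n, sfp$n_angular) else NULL
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    res <- hhat_chunk(h[ii], k[ii], l[ii], load, sfp, cp, n_time, t_I,
                      return_sf)
    H[ii] <- res$H / Hs_abs
    if (return_sf) ybar[ii, ] <- res$ybar
  }
  if (return_sf) list(H_hat = H, ybar = ybar, phi_grid = phi_grid(sfp$n_angular))
  else H
}

# Vectorized solve of the protein-conservation equation
#   N_u + pi * mean_phi( min(eta_max, (N_u/pi) exp(chi)) * n_hat ) = 1
# over many states at once. The left side is piecewise linear, increasing
# and concave in N_u, so Newton iteration from the uncapped solution
# converges monotonically (finitely many breakpoints); 40 iterations are
# far more than ever needed and the residual is checked.
solve_unbound <- function(ex, n_hat, eta_max) {
  I0 <- rowMeans(ex * n_hat)
  Nu <- 1 / (1 + I0)
  if (is.infinite(eta_max)) return(Nu)
  for (it in 1:40) {
    scaled <- sweep(ex, 1, Nu / pi, `*`)
    uncapped <- scaled < eta_max
    g <- Nu + pi * rowMeans(pmin(eta_max, scaled) * n_hat) - 1
    if (all(abs(g) < 1e-13)) break
    gp <- 1 + rowMeans(ex * n_hat * uncapped)
    Nu <- Nu - g / gp
  }
  if (any(abs(g) > 1e-10))
    stop("unbound-fraction solve did not converge; max residual ",
         signif(max(abs(g)), 3))
  Nu
}

hhat_chunk <- function(h, k, l, load, sfp, cp, n_time, t_I, return_sf) {
  n <- length(h)
  g <- geometry_from_coeffs(h, k, l)
  a1 <- g$a1_hat; a2 <- g$a2_hat; theta <- g$theta
  phi <- phi_grid(sfp$n_angular)
  nphi <- length(phi)

  # fiber strain and functional units: [n x nphi], time-independent
  sphi <- matrix(sin(phi), n, nphi, byrow = TRUE)
  cphi <- matrix(cos(phi), n, nphi, byrow = TRUE)
  psi <- atan2(a1 * sphi, a2 * cphi)
  lam_f <- sqrt(a1^2 * cos(psi)^2 + a2^2 * sin(psi)^2)
  n_hat <- lam_f / (1 + sfp$eps_ss)

  # global fiber angle delta = phi + theta: rate resolution factors
  delta <- sweep(matrix(phi, n, nphi, byrow = TRUE), 1, theta, `+`)
  cd2 <- cos(delta)^2
  rate_dir <- cd2 - load$r * (1 - cd2)   # times deps1(t) gives fiber rate

  alpha <- sfp$omega * sfp$sigma_max / sfp$kT
  dmu <- (sfp$mu_u0 - sfp$mu_b0) / sfp$kT
  mub0_hat <- sfp$mu_b0 / sfp$kT
  muu0_hat <- sfp$mu_u0 / sfp$kT

  static <- load$f == 0 || load$eps_amp == 0
  times <- if (static) 0 else t_I + (seq_len(n_time) - 1) * load$T_p / n_time

  # Slow SF remodeling (T_intra ~ T_p): the fiber distribution cannot track
  # individual cycles, so it equilibrates against the cycle-averaged Hill
  # stress. <f_v>(phi) is the trapezoidal average over one period (exact
  # mean on the periodic grid); the time average of the enthalpy in Eq-9
  # style quadrature then collapses to a single evaluation because the
  # enthalpy is linear in f_v and eta is fixed within the cycle.
  fvbar <- 0
  for (t in times) {
    deps1 <- (load$eps_amp / 2) * 2 * pi * load$f * cos(2 * pi * load$f * t)
    fvbar <- fvbar +
      pmin(1, pmax(0, 1 + sfp$k_v * (deps1 * rate_dir) / sfp$eps_rate_0))
  }
  fvbar <- fvbar / length(times)
  # functional units remodel with the sustained (cycle-averaged) tension:
  # fibers that spend part of the cycle unloaded hold fewer units
  n_eff <- n_hat * fvbar
  chi <- n_eff * (alpha * fvbar + dmu)
  ex <- exp(chi)
  N_u <- solve_unbound(ex, n_eff, sfp$eta_max)
  y <- pmin(sfp$eta_max, (N_u / pi) * ex) * n_eff
  # H_cyto / (n_T kT): pi*mean() is the plain angular integral; each
  # functional unit carries the (stress-work lowered) bound potential
  enth <- pi * rowMeans(y * n_eff * (mub0_hat - alpha * fvbar))
  ylogy <- ifelse(y > 0, y * log(y), 0)
  mix <- N_u * log(N_u) + pi * rowMeans(ylogy)
  Hcyto <- sfp$n_T * (sfp$mu_ref + sfp$kT * (enth + N_u * muu0_hat + mix))
  res <- list(H = Hcyto + passive_energy_ab(a1, a2, cp))
  if (return_sf) res$ybar <- y
  res
}
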