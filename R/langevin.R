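#' Langevin integration settings
#'
#' Settings for the overdamped Langevin evolution of the ellipse
#' coefficients `r = (h, k, l)` in nondimensional time
#' `t_hat = t |H_s| / gamma`:
#' \deqn{\Delta r_i = -\frac{\partial \hat H}{\partial r_i}\Delta\hat t
#'   + \sqrt{2\Delta\hat t/\hat\beta}\,\mathcal N(0,1).}
#'
#' @param dt_hat Nondimensional time step (> 0).
#' @param t_end_hat Simulation horizon in `t_hat`.
#' @param n_traj Number of trajectories.
#' @param seed Base RNG seed.
#' @param gamma_over_Hs Damping coefficient `gamma / |H_s|` in seconds;
#'   maps `t_hat` to wall-clock time (`t = t_hat * gamma_over_Hs`).
#' @param fd_step Finite-difference step for energy gradients in `(h,k,l)`.
#' @param record_every Record a state slice every this many steps.
#' @return An object of class `"langevin_settings"`.
#' @export
langevin_settings <- function(dt_hat = 1e-3, t_end_hat = 100, n_traj = 200,
                              seed = 1, gamma_over_Hs = 500, fd_step = 1e-4,
                              record_every = 100L) {
  stopifnot(dt_hat > 0, t_end_hat > 0, n_traj >= 1, record_every >= 1,
            fd_step > 0, gamma_over_Hs > 0)
  structure(list(dt_hat = dt_hat, t_end_hat = t_end_hat,
                 n_traj = as.integer(n_traj), seed = as.integer(seed),
                 gamma_over_Hs = gamma_over_Hs, fd_step = fd_step,
                 record_every = as.integer(record_every)),
            class = "langevin_settings")
}

#' Drift of the Langevin equation
#'
#' `-dH_hat/d(h,k,l)` by central finite differences of the cycle-averaged
#' normalized energy (error `O(fd_step^2)`). If a stencil point leaves the
#' valid-ellipse region a one-sided difference is used for that coordinate
#' and flagged in the `"one_sided"` attribute.
#'
#' @param m A `"microstate"` object.
#' @param load,sfp,cp Model objects.
#' @param fd_step Finite-difference step.
#' @param n_time Cycle-quadrature instants.
#' @param energy_fn Optional replacement energy: a function `(h, k, l) ->
#'   H_hat` (vectorized), e.g. a plug-in test landscape or a grid
#'   interpolant. Defaults to the model energy.
#' @return Numeric length-3 drift vector (named `h`, `k`, `l`).
#' @export
drift <- function(m, load, sfp, cp, fd_step = 1e-4, n_time = 64,
                  energy_fn = NULL) {
  stopifnot(inherits(m, "microstate"))
  if (is.null(energy_fn)) {
    cp <- with_suspension_energy(sfp, cp)
    energy_fn <- function(h, k, l)
      hhat_cells(h, k, l, load, sfp, cp, n_time = n_time)
  }
  r <- c(m$h, m$k, m$l)
  g <- numeric(3)
  one_sided <- logical(3)
  valid <- function(v) isTRUE(v[1] > 0 && v[3] > 0 && 4 * v[1] * v[3] - v[2]^2 > 0)
  for (i in 1:3) {
    rp <- r; rp[i] <- r[i] + fd_step
    rm <- r; rm[i] <- r[i] - fd_step
    vp <- valid(rp); vm <- valid(rm)
    if (vp && vm) {
      g[i] <- (energy_fn(rp[1], rp[2], rp[3]) -
                 energy_fn(rm[1], rm[2], rm[3])) / (2 * fd_step)
    } else if (vp) {
      g[i] <- (energy_fn(rp[1], rp[2], rp[3]) -
                 energy_fn(r[1], r[2], r[3])) / fd_step
      one_sided[i] <- TRUE
    } else if (vm) {
      g[i] <- (energy_fn(r[1], r[2], r[3]) -
                 energy_fn(rm[1], rm[2], rm[3])) / fd_step
      one_sided[i] <- TRUE
    } else stop("finite-difference stencil leaves the valid region on both sides")
  }
  out <- -g
  names(out) <- c("h", "k", "l")
  attr(out, "one_sided") <- one_sided
  out
}

#' Precompute a trilinear interpolant of the energy landscape
#'
#' Evaluates the cycle-averaged normalized energy on a regular `(h, k, l)`
#' grid once, so that Langevin trajectories can query energies and
#' gradients cheaply. Nodes that are not valid ellipses (degenerate
#' quadratic forms) are filled with a constant penalty above the maximum
#' valid energy; trajectories never enter that region because invalid
#' proposals are rejected, the penalty only makes boundary cells repulsive.
#'
#' @param load,sfp,cp Model objects.
#' @param n_grid Nodes per dimension (length 1 or 3).
#' @param a_min,a_max Semi-axis range the grid box must cover.
#' @param n_time Cycle-quadrature instants per node.
#' @return An object of class `"energy_interp"` with `$value(h, k, l)` and
#'   `$gradient(r)` (matrix in, matrix out) accessors.
#' @export
build_energy_interp <- function(load, sfp, cp, n_grid = c(101L, 121L, 101L),
                                a_min = 0.3,
                                a_max = 4, n_time = 64) {
  cp <- with_suspension_energy(sfp, cp)
  n_grid <- rep(as.integer(n_grid), length.out = 3)
  lo_hl <- 1 / a_max^2 * 0.8
  hi_hl <- 1 / a_min^2 * 1.02
  kmax <- (1 / a_min^2 - 1 / a_max^2) * 1.02
  # h and l are log-spaced: the energy varies fastest (and the validity
  # boundary 4hl > k^2 sits) at small coefficient values, where large
  # spread cells live
  hs <- exp(seq(log(lo_hl), log(hi_hl), length.out = n_grid[1]))
  ks <- seq(-kmax, kmax, length.out = n_grid[2])
  ls <- exp(seq(log(lo_hl), log(hi_hl), length.out = n_grid[3]))
  gr <- expand.grid(h = hs, k = ks, l = ls)
  # Nodes outside the resolvable-ellipse region (degenerate forms or
  # semi-axes beyond a generous margin) are filled by evaluating the energy
  # at the nearest admissible state (eigenvalues clamped, principal angle
  # kept) plus a quadratic penalty on the clamp distance. This keeps the
  # interpolant smooth across the rejection boundary, so trajectories in
  # boundary cells feel a well-defined inward drift instead of artifacts
  # of a discontinuous fill.
  s <- (gr$h + gr$l) / 2
  q <- sqrt(((gr$h - gr$l) / 2)^2 + (gr$k / 2)^2)
  lam_lo <- 1 / (a_max * 1.5)^2   # clamp bounds, beyond the rejection box
  lam_hi <- 1 / (a_min / 1.5)^2
  lam1 <- pmin(pmax(s - q, lam_lo), lam_hi * 0.99)
  lam2 <- pmin(pmax(s + q, lam1 * (1 + 1e-9)), lam_hi)
  viol <- (pmax(lam_lo - (s - q), 0) + pmax((s + q) - lam_hi, 0))^2
  ang <- principal_angle(gr$h, gr$k, gr$l)
  co <- coeffs_from_geometry(1 / sqrt(lam1), 1 / sqrt(lam2), ang)
  H <- hhat_cells(co$h, co$k, co$l, load, sfp, cp, n_time = n_time) + 25 * viol
  arr <- array(H, dim = n_grid)
  obj <- list(h = hs, k = ks, l = ls, H = arr,
              dx = c(log(hs[2]) - log(hs[1]), ks[2] - ks[1],
                     log(ls[2]) - log(ls[1])),
              lo = c(log(hs[1]), ks[1], log(ls[1])), n = n_grid,
              H_s = cp$H_s, load = load)
  class(obj) <- "energy_interp"
  obj
}

# Trilinear value and analytic within-cell gradient on the
# (log h, k, log l) grid; r is [n x 3] in raw coordinates.
interp_eval <- function(obj, r, gradient = FALSE) {
  n <- nrow(r)
  rt <- cbind(log(r[, 1]), r[, 2], log(r[, 3]))
  u <- sweep(sweep(rt, 2, obj$lo, `-`), 2, obj$dx, `/`)
  i <- pmin(pmax(floor(u), 0), matrix(obj$n - 2, n, 3, byrow = TRUE))
  f <- u - i
  f <- pmin(pmax(f, 0), 1)
  n1 <- obj$n[1]; n12 <- obj$n[1] * obj$n[2]
  base <- 1 + i[, 1] + n1 * i[, 2] + n12 * i[, 3]
  Hv <- obj$H
  c000 <- Hv[base];            c100 <- Hv[base + 1]
  c010 <- Hv[base + n1];       c110 <- Hv[base + n1 + 1]
  c001 <- Hv[base + n12];      c101 <- Hv[base + n12 + 1]
  c011 <- Hv[base + n1 + n12]; c111 <- Hv[base + n1 + n12 + 1]
  f1 <- f[, 1]; f2 <- f[, 2]; f3 <- f[, 3]
  c00 <- c000 + f1 * (c100 - c000)
  c10 <- c010 + f1 * (c110 - c010)
  c01 <- c001 + f1 * (c101 - c001)
  c11 <- c011 + f1 * (c111 - c011)
  c0 <- c00 + f2 * (c10 - c00)
  c1 <- c01 + f2 * (c11 - c01)
  val <- c0 + f3 * (c1 - c0)
  if (!gradient) return(val)
  d00 <- c100 - c000; d10 <- c110 - c010; d01 <- c101 - c001; d11 <- c111 - c011
  g1 <- ((d00 + f2 * (d10 - d00)) * (1 - f3) +
           (d01 + f2 * (d11 - d01)) * f3) / obj$dx[1]
  g2 <- ((c10 - c00) * (1 - f3) + (c11 - c01) * f3) / obj$dx[2]
  g3 <- (c1 - c0) / obj$dx[3]
  # chain rule back to raw coordinates for the log-spaced dimensions
  list(value = val, grad = cbind(g1 / r[, 1], g2, g3 / r[, 3]))
}

#' @export
print.energy_interp <- function(x, ...) {
  cat(sprintf("<energy_interp> %d x %d x %d grid over (h, k, l); H_hat range [%.3g, %.3g]\n",
              x$n[1], x$n[2], x$n[3], min(x$H), max(x$H)))
  invisible(x)
}

# principal-axis angle of the quadratic form, in (-pi/2, pi/2]
principal_angle <- function(h, k, l) 0.5 * atan2(-k, l - h)

# wrap an angular difference into (-pi/2, pi/2]
wrap_half <- function(x) {
  y <- (x + pi / 2) %% pi - pi / 2
  ifelse(y == -pi / 2, pi / 2, y)
}

# Core vectorized Euler-Maruyama engine over n trajectories.
# grad_fn: function([n x 3]) -> [n x 3] gradient of H_hat.
# Returns recorded slices including unwrapped material-axis rotation.
langevin_engine <- function(r0, grad_fn, beta_hat, settings,
                            a_min = 0.3, a_max = 4, max_reject = 100L) {
  n <- nrow(r0)
  n_steps <- ceiling(settings$t_end_hat / settings$dt_hat)
  rec <- settings$record_every
  n_slices <- floor(n_steps / rec) + 1L
  dt <- settings$dt_hat
  amp <- sqrt(2 * dt / beta_hat)

  valid_rows <- function(r) {
    disc <- 4 * r[, 1] * r[, 3] - r[, 2]^2
    ok <- r[, 1] > 0 & r[, 3] > 0 & disc > 0
    s <- (r[, 1] + r[, 3]) / 2
    q <- sqrt(pmax(((r[, 1] - r[, 3]) / 2)^2 + (r[, 2] / 2)^2, 0))
    lam_min <- s - q
    lam_max <- s + q
    ok & lam_min > 1 / a_max^2 & lam_max < 1 / a_min^2
  }
  if (!all(valid_rows(r0))) stop("invalid initial states")

  out_t <- (0:(n_slices - 1)) * rec * dt
  TH <- TR <- H1 <- K1 <- L1 <- matrix(NA_real_, n, n_slices)

  r <- r0
  psi <- principal_angle(r[, 1], r[, 2], r[, 3]) # tracked material axis
  theta_r <- numeric(n)

  record <- function(slot) {
    H1[, slot] <<- r[, 1]; K1[, slot] <<- r[, 2]; L1[, slot] <<- r[, 3]
    TH[, slot] <<- principal_angle(r[, 1], r[, 2], r[, 3]) %% pi
    TR[, slot] <<- theta_r
  }
  record(1L)

  set.seed(settings$seed)
  for (step in seq_len(n_steps)) {
    g <- grad_fn(r)
    mu <- r - dt * g
    prop <- mu + amp * matrix(stats::rnorm(3L * n), n, 3)
    bad <- !valid_rows(prop)
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > max_reject)
        stop("step-size error: > ", max_reject, " rejected proposals; reduce dt_hat")
      nb <- sum(bad)
      prop[bad, ] <- mu[bad, , drop = FALSE] +
        amp * matrix(stats::rnorm(3L * nb), nb, 3)
      bad[bad] <- !valid_rows(prop[bad, , drop = FALSE])
    }
    r <- prop
    # material-axis tracking: pick whichever principal axis is closer to
    # the tracked axis, so axis swaps at As = 1 record no spurious rotation.
    # While the state is nearly circular the principal direction is
    # ill-conditioned (angle jumps are numerical noise), so the tracked
    # axis is frozen until the shape re-elongates.
    pa <- principal_angle(r[, 1], r[, 2], r[, 3])
    s2 <- (r[, 1] + r[, 3]) / 2
    q2 <- sqrt(((r[, 1] - r[, 3]) / 2)^2 + (r[, 2] / 2)^2)
    elongated <- q2 > 0.05 * s2 # aspect ratio above ~1.05
    d1 <- wrap_half(pa - psi)
    d2 <- wrap_half(pa + pi / 2 - psi)
    dpsi <- ifelse(abs(d1) <= abs(d2), d1, d2) * elongated
    psi <- psi + dpsi
    theta_r <- theta_r + dpsi
    if (step %% rec == 0L) record(step %/% rec + 1L)
  }
  structure(list(times = out_t, h = H1, k = K1, l = L1, theta = TH,
                 theta_r = TR, settings = settings, beta_hat = beta_hat),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d trajectories, %d recorded slices to t_hat = %g (dt_hat = %g)\n",
              nrow(x$theta), length(x$times), max(x$times), x$settings$dt_hat))
  invisible(x)
}

#' Run a single Langevin trajectory
#'
#' Integrates one seeded path of the overdamped Langevin equation and
#' records morphology and accumulated rigid rotation. With
#' `energy_interp = NULL` the drift is computed by central finite
#' differences of the exact cycle-averaged energy at every step (accurate
#' but slow; intended for short runs and tests). Supplying a prebuilt
#' [build_energy_interp()] object makes long runs cheap.
#'
#' @param initial A `"microstate"` object.
#' @param settings A [langevin_settings()] object (`n_traj` ignored).
#' @param load,sfp,cp Model objects.
#' @param beta_hat Nondimensional inverse homeostatic temperature.
#' @param energy_interp Optional `"energy_interp"` object.
#' @param n_time Cycle-quadrature instants for exact drift.
#' @return An object of class `"trajectory"`: list with `times` (t_hat),
#'   `states` data frame (`h,k,l,a1_hat,a2_hat,theta`), `theta_r`
#'   (accumulated rotation, rad), and `theta_r_aux` (`theta_r` folded to
#'   `[0, pi)`).
#' @export
run_trajectory <- function(initial, settings, load, sfp, cp, beta_hat,
                           energy_interp = NULL, n_time = 64) {
  stopifnot(inherits(initial, "microstate"),
            inherits(settings, "langevin_settings"))
  grad_fn <- make_grad_fn(load, sfp, cp, energy_interp, settings$fd_step, n_time)
  eng <- langevin_engine(matrix(c(initial$h, initial$k, initial$l), 1, 3),
                         grad_fn, beta_hat, settings)
  g <- geometry_from_coeffs(as.numeric(eng$h), as.numeric(eng$k), as.numeric(eng$l))
  structure(list(times = eng$times,
                 states = data.frame(h = as.numeric(eng$h), k = as.numeric(eng$k),
                                     l = as.numeric(eng$l), a1_hat = g$a1_hat,
                                     a2_hat = g$a2_hat, theta = g$theta),
                 theta_r = as.numeric(eng$theta_r),
                 theta_r_aux = as.numeric(eng$theta_r) %% pi,
                 settings = settings),
            class = "trajectory")
}

#' Single Euler-Maruyama update of a microstate
#'
#' One step of the overdamped Langevin discretization,
#' `r <- r + dt_hat * drift + sqrt(2 dt_hat / beta_hat) * noise`,
#' applied to the ellipse coefficients. Proposals that leave the valid
#' ellipse region are rejected and the noise resampled.
#'
#' @param m A `"microstate"` object.
#' @param drift Length-3 drift vector `-dH_hat/d(h,k,l)` (see [drift()]).
#' @param beta_hat Inverse homeostatic temperature (use `Inf` for
#'   deterministic descent).
#' @param dt_hat Time step.
#' @param noise Optional length-3 standard-normal draw; fresh draws are
#'   taken from the current RNG stream when `NULL` (and on rejection).
#' @param max_reject Maximum rejection-resampling attempts.
#' @return The updated `"microstate"`.
#' @export
langevin_step <- function(m, drift, beta_hat, dt_hat = 1e-3, noise = NULL,
                          max_reject = 100L) {
  stopifnot(inherits(m, "microstate"), length(drift) == 3, dt_hat > 0)
  r <- c(m$h, m$k, m$l)
  amp <- if (is.infinite(beta_hat)) 0 else sqrt(2 * dt_hat / beta_hat)
  mu <- r + dt_hat * as.numeric(drift)
  if (is.null(noise)) noise <- stats::rnorm(3)
  stopifnot(length(noise) == 3)
  for (try in seq_len(max_reject)) {
    prop <- mu + amp * noise
    if (prop[1] > 0 && prop[3] > 0 && 4 * prop[1] * prop[3] - prop[2]^2 > 0)
      return(microstate(prop[1], prop[2], prop[3]))
    if (amp == 0) stop("deterministic step leaves the valid region")
    noise <- stats::rnorm(3)
  }
  stop("step-size error: > ", max_reject, " rejected proposals; reduce dt_hat")
}

make_grad_fn <- function(load, sfp, cp, energy_interp, fd_step, n_time) {
  if (!is.null(energy_interp)) {
    function(r) interp_eval(energy_interp, r, gradient = TRUE)$grad
  } else {
    cp <- with_suspension_energy(sfp, cp)
    function(r) {
      n <- nrow(r)
      g <- matrix(0, n, 3)
      for (i in 1:3) {
        rp <- r; rp[, i] <- r[, i] + fd_step
        rm <- r; rm[, i] <- r[, i] - fd_step
        g[, i] <- (hhat_cells(rp[, 1], rp[, 2], rp[, 3], load, sfp, cp, n_time = n_time) -
                     hhat_cells(rm[, 1], rm[, 2], rm[, 3], load, sfp, cp, n_time = n_time)) /
          (2 * fd_step)
      }
      g
    }
  }
}

#' Run a Langevin trajectory ensemble
#'
#' Simulates many seeded trajectories from one of the initial-condition
#' protocols:
#' \describe{
#'   \item{`"suspension"`}{all cells start as the suspended circle of
#'     radius `0.96 R0` (orientation undefined; reported uniformly).}
#'   \item{`"equilibrated"`}{shape couplets `(A_hat, As)` are drawn from
#'     the static (`f = 0`) equilibrium ensemble and every cell is oriented
#'     at `theta0`; cyclic straining starts at `t_hat = 0`. This is the
#'     protocol used to separate rotation-mode from strain-mode
#'     reorientation.}
#'   \item{`"explicit"`}{a user-supplied matrix of `(h, k, l)` rows.}
#' }
#'
#' @param initial_spec A list with element `kind` (one of the above) and,
#'   for `"equilibrated"`, `theta0` (rad) and optionally `n_morphologies`;
#'   for `"explicit"`, `states` (`n x 3` matrix).
#' @param settings A [langevin_settings()] object.
#' @param load,sfp,cp Model objects.
#' @param beta_hat Inverse homeostatic temperature for the noise amplitude;
#'   if `NULL` it is solved from a sampled ensemble under `load`.
#' @param energy_interp Optional prebuilt [build_energy_interp()] grid;
#'   built automatically when `NULL`.
#' @param static_ensemble Optional precomputed static `"ensemble_result"`
#'   for the `"equilibrated"` protocol.
#' @param n_time Cycle-quadrature instants.
#' @return A `"trajectory_ensemble"`: recorded slice matrices
#'   (`h,k,l,theta,theta_r`, trajectories x slices), slice times, settings.
#' @export
run_langevin_ensemble <- function(initial_spec, settings, load, sfp, cp,
                                  beta_hat = NULL, energy_interp = NULL,
                                  static_ensemble = NULL, n_time = 64) {
  stopifnot(inherits(settings, "langevin_settings"))
  cp <- with_suspension_energy(sfp, cp)
  n <- settings$n_traj
  r0 <- switch(initial_spec$kind,
    suspension = {
      a <- cp$suspension_radius_factor
      matrix(rep(c(1 / a^2, 0, 1 / a^2), each = n), n, 3)
    },
    equilibrated = {
      if (is.null(static_ensemble))
        static_ensemble <- homeostatic_ensemble(cyclic_load(eps_amp = 0, f = 0),
                                                sfp, cp,
                                                n_samples = 20000,
                                                seed = settings$seed + 1L)
      nm <- initial_spec$n_morphologies %||% 50L
      set.seed(settings$seed + 2L)
      pick <- sample.int(nrow(static_ensemble$samples), nm, replace = TRUE,
                         prob = static_ensemble$samples$weight)
      reps <- rep(pick, length.out = n)
      a1 <- static_ensemble$samples$a1_hat[reps]
      a2 <- static_ensemble$samples$a2_hat[reps]
      co <- coeffs_from_geometry(a1, a2, rep(initial_spec$theta0, n))
      cbind(co$h, co$k, co$l)
    },
    explicit = {
      st <- initial_spec$states
      stopifnot(is.matrix(st), ncol(st) == 3)
      matrix(st[rep(seq_len(nrow(st)), length.out = n), ], n, 3)
    },
    stop("unknown initial_spec kind: ", initial_spec$kind)
  )
  if (is.null(beta_hat)) {
    ens <- homeostatic_ensemble(load, sfp, cp, n_samples = 20000,
                                seed = settings$seed + 3L, n_time = n_time)
    beta_hat <- ens$beta_hat
  }
  if (is.null(energy_interp))
    energy_interp <- build_energy_interp(load, sfp, cp, n_time = n_time)
  grad_fn <- function(r) interp_eval(energy_interp, r, gradient = TRUE)$grad
  langevin_engine(r0, grad_fn, beta_hat, settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

slice_index <- function(ens, t_hat) {
  i <- which.min(abs(ens$times - t_hat))
  if (abs(ens$times[i] - t_hat) > ens$settings$dt_hat * ens$settings$record_every)
    warning("nearest recorded slice is at t_hat = ", ens$times[i])
  i
}

#' Orientational order parameter at a time slice
#'
#' `S = <cos(2 theta)>` over trajectories: +1 for alignment with the
#' straining axis, -1 for perpendicular alignment, 0 for isotropy.
#'
#' @param ens A `"trajectory_ensemble"`.
#' @param t_hat Nondimensional time of the slice.
#' @return Scalar `S`.
#' @export
order_parameter <- function(ens, t_hat) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  mean(cos(2 * ens$theta[, slice_index(ens, t_hat)]))
}

#' Strain-mode versus rotation-mode quantification
#'
#' At a steady-state slice, compares the mass of the orientation density
#' `p(theta)` inside an angular window with the mass of the folded-rotation
#' density `p(theta_r_aux)` (`theta_r` shifted by multiples of pi into
#' `[0, pi)`). Cells that reoriented by rigid rotation carry their
#' `theta_r_aux` into the window; cells that reoriented by the strain mode
#' (axis swap without rotation) do not. The difference is the strain-mode
#' fraction.
#'
#' @param ens A `"trajectory_ensemble"` (typically from a `theta0 = 0`
#'   equilibrated start).
#' @param t_hat Slice time.
#' @param window Angular window in radians (default 40 to 140 degrees).
#' @return Named vector: `P_theta_in_window`, `P_aux_in_window`,
#'   `strain_mode_fraction`.
#' @export
mode_fraction <- function(ens, t_hat = 100,
                          window = c(40, 140) * pi / 180) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  i <- slice_index(ens, t_hat)
  th <- ens$theta[, i]
  aux <- ens$theta_r[, i] %% pi
  P_theta <- mean(th >= window[1] & th <= window[2])
  P_aux <- mean(aux >= window[1] & aux <= window[2])
  c(P_theta_in_window = P_theta, P_aux_in_window = P_aux,
    strain_mode_fraction = P_theta - P_aux)
}

#' Check Langevin stationarity against the Boltzmann law
#'
#' Bins late-time Langevin occupancy over `(h, k, l)` and compares it with
#' the equilibrium probability `exp(-beta_hat H_hat)/Z` integrated over the
#' same bins (by uniform quadrature on a node set restricted to the valid
#' sampled region). This is the discrete check that the stationary solution
#' of the Fokker-Planck equation associated with the simulated dynamics is
#' the homeostatic equilibrium distribution.
#'
#' @param states An `n x 3` matrix of visited `(h, k, l)` states (pooled
#'   late-time slices).
#' @param energy_fn Vectorized function `(h, k, l) -> H_hat`.
#' @param beta_hat Inverse homeostatic temperature of the reference law.
#' @param n_bins Bins per coordinate.
#' @param n_quad Quadrature nodes per coordinate for the reference measure.
#' @param a_min,a_max Semi-axis bounds defining the support.
#' @param kl_threshold Pass threshold on the KL divergence (nats).
#' @return A list: `kl`, `chisq`, `dof`, `n_occupied_bins`, `pass`.
#' @export
stationarity_check <- function(states, energy_fn, beta_hat, n_bins = 5,
                               n_quad = 41, a_min = 0.3, a_max = 4,
                               kl_threshold = 0.05) {
  stopifnot(is.matrix(states), ncol(states) == 3)
  rng <- apply(states, 2, range)
  pad <- 1e-9 + 0.02 * (rng[2, ] - rng[1, ])
  lo <- rng[1, ] - pad
  hi <- rng[2, ] + pad
  brk <- lapply(1:3, function(i) seq(lo[i], hi[i], length.out = n_bins + 1))
  bin_of <- function(x, b) pmin(pmax(findInterval(x, b, all.inside = TRUE), 1), n_bins)
  ib <- sapply(1:3, function(i) bin_of(states[, i], brk[[i]]))
  code <- (ib[, 1] - 1) + n_bins * (ib[, 2] - 1) + n_bins^2 * (ib[, 3] - 1)
  occ <- tabulate(code + 1L, nbins = n_bins^3)

  qs <- lapply(1:3, function(i) {
    m <- (brk[[i]][-1] + brk[[i]][-(n_bins + 1)]) / 2
    st <- diff(brk[[i]]) / n_quad
    as.vector(sapply(seq_len(n_bins), function(j)
      brk[[i]][j] + (seq_len(n_quad) - 0.5) * st[j]))
  })
  nodes <- expand.grid(h = qs[[1]], k = qs[[2]], l = qs[[3]])
  okn <- valid_coeffs(nodes$h, nodes$k, nodes$l, a_min, a_max)
  wq <- numeric(nrow(nodes))
  wq[okn] <- exp(-beta_hat * (energy_fn(nodes$h[okn], nodes$k[okn], nodes$l[okn]) -
                                min(energy_fn(states[, 1], states[, 2], states[, 3]))))
  nb1 <- (findInterval(nodes$h, brk[[1]], all.inside = TRUE))
  nb2 <- (findInterval(nodes$k, brk[[2]], all.inside = TRUE))
  nb3 <- (findInterval(nodes$l, brk[[3]], all.inside = TRUE))
  ncode <- (nb1 - 1) + n_bins * (nb2 - 1) + n_bins^2 * (nb3 - 1)
  Emass <- vapply(seq_len(n_bins^3) - 1L, function(cd) sum(wq[ncode == cd]), 0)
  Emass <- Emass / sum(Emass)

  keep <- Emass > 1e-12 | occ > 0
  p_emp <- occ[keep] / sum(occ)
  p_ref <- Emass[keep]
  p_ref <- p_ref / sum(p_ref)
  nz <- p_emp > 0 & p_ref > 0
  kl <- sum(p_emp[nz] * log(p_emp[nz] / p_ref[nz]))
  Ecnt <- p_ref * sum(occ)
  use <- Ecnt > 5
  chisq <- sum((occ[keep][use] - Ecnt[use])^2 / Ecnt[use])
  list(kl = kl, chisq = chisq, dof = sum(use) - 1,
       n_occupied_bins = sum(occ > 0), pass = kl < kl_threshold)
}
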