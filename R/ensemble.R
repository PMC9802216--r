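#' Sample the morphological phase space
#'
#' Draws microstates uniformly in the ellipse-coefficient box `(h, k, l)`
#' and rejects draws that are not valid ellipses or whose semi-axes fall
#' outside `[a_min, a_max]` (in units of `R0`). Sampling uniformly in the
#' coefficients — rather than in `(A, As, theta)` — is the measure in which
#' the ensemble is defined; reported morphology densities carry the induced
#' Jacobian implicitly.
#'
#' @param n_samples Number of accepted samples to return.
#' @param seed Integer RNG seed (local to this call).
#' @param a_min,a_max Bounds on the normalized semi-axes.
#' @param bounds Optional list with elements `h`, `k`, `l`, each a
#'   length-2 numeric range for the proposal box. Defaults to the tight box
#'   implied by `[a_min, a_max]`.
#' @return A data frame with columns `h`, `k`, `l`, `a1_hat`, `a2_hat`,
#'   `theta`, `A_hat`, `As`, and an attribute `acceptance` (the acceptance
#'   fraction of the rejection sampler).
#' @export
sample_phase_space <- function(n_samples, seed, a_min = 0.3, a_max = 4,
                               bounds = NULL) {
  stopifnot(n_samples >= 1, a_min > 0, a_max > a_min)
  if (is.null(bounds)) {
    lo <- 1 / a_max^2
    hi <- 1 / a_min^2
    bounds <- list(h = c(lo, hi), k = c(-(hi - lo), hi - lo), l = c(lo, hi))
  }
  acc_h <- acc_k <- acc_l <- numeric(0)
  n_prop <- 0L
  n_draw <- max(4L * n_samples, 1000L)
  withr_seed <- function(expr) { # localized RNG, leaves global state alone
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  withr_seed({
    while (length(acc_h) < n_samples) {
      h <- stats::runif(n_draw, bounds$h[1], bounds$h[2])
      k <- stats::runif(n_draw, bounds$k[1], bounds$k[2])
      l <- stats::runif(n_draw, bounds$l[1], bounds$l[2])
      ok <- valid_coeffs(h, k, l, a_min, a_max)
      n_prop <- n_prop + n_draw
      acc_h <- c(acc_h, h[ok]); acc_k <- c(acc_k, k[ok]); acc_l <- c(acc_l, l[ok])
      if (n_prop > 1000L && length(acc_h) == 0L)
        stop("phase-space bounds error: no valid ellipses in the proposal box")
    }
  })
  keep <- seq_len(n_samples)
  h <- acc_h[keep]; k <- acc_k[keep]; l <- acc_l[keep]
  g <- geometry_from_coeffs(h, k, l)
  out <- data.frame(h = h, k = k, l = l, a1_hat = g$a1_hat, a2_hat = g$a2_hat,
                    theta = g$theta, A_hat = g$a1_hat * g$a2_hat,
                    As = g$a1_hat / g$a2_hat)
  attr(out, "acceptance") <- length(acc_h) / n_prop
  attr(out, "seed") <- seed
  out
}

#' Boltzmann weights at a given inverse homeostatic temperature
#'
#' `w_c` proportional to `exp(-beta_hat * H_hat_c)`, normalized to sum to 1.
#' Computed after subtracting the minimum energy so the exponentials cannot
#' overflow.
#'
#' @param energies Normalized cycle-averaged energies `H_hat`.
#' @param beta_hat Nondimensional distribution parameter `beta * |H_s|`.
#' @return Weights summing to 1.
#' @export
equilibrium_weights <- function(energies, beta_hat) {
  if (any(!is.finite(energies))) stop("non-finite energies")
  w <- exp(-beta_hat * (energies - min(energies)))
  w / sum(w)
}

#' Solve the homeostatic constraint for beta
#'
#' Finds the nondimensional distribution parameter `beta_hat = beta |H_s|`
#' such that the ensemble-average normalized energy equals the suspension
#' value:
#' \deqn{\langle \hat H\rangle_\beta = \mathrm{sign}(H_s)\cdot 1.}
#' Because `<H_hat>_beta` is strictly decreasing in `beta_hat`, the root is
#' unique; it is found by expanding-bracket bisection
#' ([stats::uniroot()]).
#'
#' @param energies Normalized energies `H_hat` of the sampled microstates.
#' @param target Normalized homeostatic target, `-1` for `H_s < 0`.
#' @param tol Residual tolerance on `<H_hat> - target`.
#' @return `beta_hat` (scalar).
#' @export
solve_beta <- function(energies, target = -1, tol = 1e-10) {
  if (any(!is.finite(energies))) stop("non-finite energies")
  rng <- range(energies)
  if (diff(rng) == 0) {
    if (abs(rng[1] - target) < tol)
      stop("degenerate constraint: all energies equal the target; any beta satisfies it")
    stop("infeasible constraint: all energies equal ", signif(rng[1], 6))
  }
  if (target <= rng[1] || target >= rng[2])
    stop(sprintf("infeasible constraint: target %.6g outside attainable range (%.6g, %.6g)",
                 target, rng[1], rng[2]))
  gap <- function(b) sum(energies * equilibrium_weights(energies, b)) - target
  # mean energy at beta = 0 is mean(energies); expand bracket in the
  # direction needed (beta > 0 when target < mean, else beta < 0)
  lo <- -1; hi <- 1
  while (gap(hi) > 0 && hi < 1e6) hi <- hi * 2
  while (gap(lo) < 0 && lo > -1e6) lo <- lo * 2
  if (gap(hi) > 0 || gap(lo) < 0)
    stop("failed to bracket the homeostatic constraint root")
  r <- stats::uniroot(gap, c(lo, hi), tol = 1e-12, maxiter = 2000)
  b <- r$root
  resid <- abs(gap(b))
  if (resid > tol)
    stop(sprintf("homeostatic constraint residual %.3g exceeds tolerance %.3g", resid, tol))
  b
}

#' Solve the cyclic homeostatic ensemble
#'
#' Convenience driver: samples the phase space, computes cycle-averaged
#' normalized energies, solves the homeostatic constraint for `beta_hat`,
#' and returns the weighted ensemble together with the per-microstate
#' cycle-averaged stress-fiber distributions needed for the order
#' statistics.
#'
#' @param load A [cyclic_load()] object.
#' @param sfp An [sf_params()] object.
#' @param cp A [cell_params()] object.
#' @param n_samples Number of accepted phase-space samples.
#' @param seed Integer RNG seed.
#' @param n_time Quadrature instants per strain cycle.
#' @param a_min,a_max Semi-axis bounds for the sampler.
#' @return An object of class `"ensemble_result"`: list with `samples`
#'   (data frame, including `H_hat` and `weight` columns), `beta_hat`,
#'   `ybar` (matrix of cycle-averaged `eta*n` per sample), `phi_grid`,
#'   `H_s`, and `meta`.
#' @examples
#' \donttest{
#' ens <- homeostatic_ensemble(cyclic_load(f = 0), sf_params(), cell_params(),
#'                             n_samples = 2000, seed = 1)
#' ens$beta_hat
#' }
#' @export
homeostatic_ensemble <- function(load, sfp, cp, n_samples = 20000, seed = 1,
                                 n_time = 64, a_min = 0.3, a_max = 4) {
  cp <- with_suspension_energy(sfp, cp)
  samp <- sample_phase_space(n_samples, seed, a_min, a_max)
  res <- hhat_cells(samp$h, samp$k, samp$l, load, sfp, cp, n_time = n_time,
                    return_sf = TRUE)
  target <- sign(cp$H_s)
  beta_hat <- solve_beta(res$H_hat, target = target)
  w <- equilibrium_weights(res$H_hat, beta_hat)
  samp$H_hat <- res$H_hat
  samp$weight <- w
  structure(list(samples = samp, beta_hat = beta_hat, ybar = res$ybar,
                 phi_grid = res$phi_grid, H_s = cp$H_s,
                 meta = list(seed = seed, n_samples = n_samples,
                             n_time = n_time, a_min = a_min, a_max = a_max,
                             load = load, acceptance = attr(samp, "acceptance"))),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d microstates; beta_hat = %.4g; H_s = %.4g\n",
              nrow(x$samples), x$beta_hat, x$H_s))
  invisible(x)
}

#' Equilibrium morphology densities
#'
#' Weighted histogram densities of orientation `theta` (on `[0, pi)`),
#' normalized area `A_hat`, and aspect ratio `As`.
#'
#' @param res An `"ensemble_result"`.
#' @param bins_theta,bins_shape Histogram bin counts.
#' @return A list of three data frames (`theta`, `A_hat`, `As`), each with
#'   bin `mid` and `density` columns normalized to unit integral.
#' @export
morphology_densities <- function(res, bins_theta = 36, bins_shape = 40) {
  stopifnot(inherits(res, "ensemble_result"))
  s <- res$samples
  wdens <- function(x, w, lo, hi, nb) {
    br <- seq(lo, hi, length.out = nb + 1)
    idx <- findInterval(pmin(pmax(x, lo), hi), br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    d <- vapply(seq_len(nb), function(i) sum(w[idx == i]), 0)
    d <- d / (sum(w) * diff(br))
    data.frame(mid = (br[-1] + br[-(nb + 1)]) / 2, density = d)
  }
  list(theta = wdens(s$theta, s$weight, 0, pi, bins_theta),
       A_hat = wdens(s$A_hat, s$weight, 0, max(s$A_hat) * 1.001, bins_shape),
       As = wdens(s$As, s$weight, 1, max(s$As) * 1.001, bins_shape))
}

#' Ensemble-averaged stress-fiber angular distributions
#'
#' Computes the global distribution
#' \deqn{\xi(\delta) = \sum_c P^{(c)}_{eq}\,\hat\eta(\phi)\hat n(\phi),\qquad
#'       \phi = \delta - \theta_c,}
#' (stress-fiber concentration at angle `delta` to the straining axis) and
#' the cell-frame distribution
#' \eqn{\rho(\phi) = \sum_c P^{(c)}_{eq} \hat\eta(\phi)\hat n(\phi)}
#' (relative to each cell's major axis). Per-microstate `eta*n` is the
#' cycle average stored in the ensemble result. Both are normalized to unit
#' integral over their pi-periodic domain.
#'
#' @param res An `"ensemble_result"`.
#' @return A list of two `"angular_density"` objects, `xi_hat` (on the
#'   global angle `delta`) and `rho_hat` (on the cell-frame angle `phi`).
#' @export
sf_global_distribution <- function(res) {
  stopifnot(inherits(res, "ensemble_result"))
  w <- res$samples$weight
  theta <- res$samples$theta
  phi <- res$phi_grid
  nphi <- length(phi)
  dphi <- pi / nphi
  rho <- colSums(res$ybar * w)

  # xi(delta_j) = sum_c w_c * ybar_c(delta_j - theta_c): periodic linear
  # interpolation of each row at the shifted angles, done by index gathers.
  shift <- (-theta) / dphi                    # fractional grid offset per cell
  i0 <- floor(shift)
  frac <- shift - i0
  cols <- matrix(seq_len(nphi), nrow = length(w), ncol = nphi, byrow = TRUE)
  jA <- ((cols - 1 + i0) %% nphi) + 1         # integer parts, wrapped
  jB <- (jA %% nphi) + 1
  rowsel <- function(J) res$ybar[cbind(rep(seq_along(w), nphi), as.vector(J))]
  yA <- matrix(rowsel(jA), length(w), nphi)
  yB <- matrix(rowsel(jB), length(w), nphi)
  xi <- colSums(((1 - frac) * yA + frac * yB) * w)

  list(xi_hat = angular_density(phi, xi / (sum(xi) * dphi)),
       rho_hat = angular_density(phi, rho / (sum(rho) * dphi)))
}

#' Angular density object
#'
#' A nonnegative density on a uniform grid over a pi-periodic angular
#' domain, normalized to unit integral.
#'
#' @param grid Angles (rad), uniform spacing.
#' @param density Nonnegative values integrating to 1.
#' @param tol Normalization tolerance.
#' @return An object of class `"angular_density"`.
#' @export
angular_density <- function(grid, density, tol = 1e-10) {
  stopifnot(length(grid) == length(density))
  if (any(density < -1e-12)) stop("density must be nonnegative")
  d <- diff(grid)
  if (max(abs(d - d[1])) > 1e-9) stop("grid must be uniform")
  tot <- sum(density) * d[1]
  if (abs(tot - 1) > max(tol, 1e-6))
    stop(sprintf("density must integrate to 1 (got %.6g)", tot))
  structure(list(grid = grid, density = pmax(density, 0), dx = d[1]),
            class = "angular_density")
}

#' Circular variance of an angular density
#'
#' For a pi-periodic angular density `d`:
#' \deqn{CV = 1 - \sqrt{\Big[\int d(\delta)\cos 2\delta\,d\delta\Big]^2 +
#'                     \Big[\int d(\delta)\sin 2\delta\,d\delta\Big]^2}.}
#' `CV = 1` for an isotropic density, `0` for perfect alignment.
#'
#' @param d An `"angular_density"` (or a list with `grid` and `density`
#'   integrating to one).
#' @return CV in `[0, 1]`.
#' @examples
#' g <- seq(-pi / 2 + pi / 360, pi / 2, length.out = 360)
#' circular_variance(angular_density(g, rep(1 / pi, 360)))  # 1: isotropic
#' @export
circular_variance <- function(d) {
  if (!inherits(d, "angular_density"))
    d <- angular_density(d$grid, d$density)
  C <- sum(d$density * cos(2 * d$grid)) * d$dx
  S <- sum(d$density * sin(2 * d$grid)) * d$dx
  1 - sqrt(C^2 + S^2)
}

#' Cycle-averaged free-energy landscape over cell shape
#'
#' Evaluates `H_hat` on a rectangular grid of normalized semi-axes
#' `(a1_hat, a2_hat)` at fixed orientation `theta`, and locates the grid
#' argmin. Grid points with `a1 < a2` mirror the `a1 >= a2` half-plane
#' (the relabeling `(a1, a2, theta) -> (a2, a1, theta + pi/2)` is an
#' identity of the model).
#'
#' @param theta Cell orientation (rad).
#' @param a1,a2 Numeric grid vectors of normalized semi-axes.
#' @param load,sfp,cp Model objects.
#' @param n_time Quadrature instants per cycle.
#' @return A list with `a1`, `a2`, matrix `H_hat` (`length(a1)` x
#'   `length(a2)`), `argmin` (named vector `a1`, `a2`, `H_hat`), and the
#'   grid resolution `res`.
#' @export
free_energy_landscape <- function(theta, a1 = seq(0.3, 3, length.out = 60),
                                  a2 = seq(0.3, 3, length.out = 60),
                                  load = cyclic_load(), sfp = sf_params(),
                                  cp = cell_params(), n_time = 64) {
  gr <- expand.grid(a1 = a1, a2 = a2)
  # swap so first axis is the major one; theta rotates by pi/2 for swapped
  swap <- gr$a1 < gr$a2
  A1 <- ifelse(swap, gr$a2, gr$a1)
  A2 <- ifelse(swap, gr$a1, gr$a2)
  TH <- ifelse(swap, theta + pi / 2, theta)
  co <- coeffs_from_geometry(A1, A2, TH)
  H <- hhat_cells(co$h, co$k, co$l, load, sfp, cp, n_time = n_time)
  Hm <- matrix(H, length(a1), length(a2))
  i <- arrayInd(which.min(Hm), dim(Hm))
  list(a1 = a1, a2 = a2, H_hat = Hm,
       argmin = c(a1 = a1[i[1]], a2 = a2[i[2]], H_hat = Hm[i]),
       res = c(a1 = if (length(a1) > 1) a1[2] - a1[1] else NA_real_,
               a2 = if (length(a2) > 1) a2[2] - a2[1] else NA_real_))
}
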