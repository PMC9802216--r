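#' Hill-type rate factor of the stress-fiber stress
#'
#' The tensile stress carried by a stress fiber is
#' `sigma = sigma_max * f_v`, with the rate factor following a Hill-type
#' relation: fibers at or above isometric conditions carry the full
#' isometric stress, while the stress drops linearly with contraction
#' (shortening) rate,
#' \deqn{f_v = 1 \ (\dot\varepsilon \ge 0),\qquad
#'       f_v = \max(0,\, 1 + k_v \dot\varepsilon/\dot\varepsilon_0)\ (\dot\varepsilon < 0).}
#'
#' @param eps_rate_fiber Fiber strain rate (1/s), vectorized. Negative
#'   values are contraction.
#' @param p An [sf_params()] object.
#' @return Rate factor(s) in `[0, 1]`.
#' @examples
#' p <- sf_params()
#' hill_factor(0, p)                        # 1: isometric
#' hill_factor(-p$eps_rate_0 / p$k_v, p)    # 0: stall rate
#' @export
hill_factor <- function(eps_rate_fiber, p) {
  stopifnot(inherits(p, "sf_params"))
  if (any(!is.finite(eps_rate_fiber))) stop("non-finite fiber strain rate")
  pmin(1, pmax(0, 1 + p$k_v * eps_rate_fiber / p$eps_rate_0))
}

#' Steady-state number of functional units in a stress fiber
#'
#' At steady state the functional units in a fiber remodel so that each unit
#' sits at its intrinsic strain `eps_ss`; a fiber at nominal strain
#' `eps_nom` therefore holds
#' \deqn{\hat n = (1 + \varepsilon_{nom})/(1 + \tilde\varepsilon^{ss}).}
#' Fibers in stretched directions pack more functional units.
#'
#' @param eps_nom_fiber Nominal fiber strain (> -1), vectorized.
#' @param p An [sf_params()] object.
#' @return Functional units per fiber, `n_hat > 0`.
#' @export
steady_units <- function(eps_nom_fiber, p) {
  stopifnot(inherits(p, "sf_params"))
  if (any(!is.finite(eps_nom_fiber))) stop("non-finite fiber strain")
  if (any(eps_nom_fiber <= -1))
    stop("invalid kinematics: fiber strain must be > -1")
  (1 + eps_nom_fiber) / (1 + p$eps_ss)
}

#' Steady-state angular stress-fiber state
#'
#' Given the fiber strain map `strain_of_phi` and strain-rate map
#' `rate_of_phi` over the angular grid, the bound SF distribution takes the
#' capped Boltzmann form
#' \deqn{\hat\eta(\phi) = \min\{\eta_{max},\,(\hat N_u/\pi)\,e^{\chi(\phi)}\},\qquad
#'  \chi(\phi) = \frac{[\Omega\sigma(\phi) + \mu_{u0} - \mu_{b0}]\,\hat n(\phi)}{kT},}
#' with `sigma(phi) = sigma_max * f_v(rate(phi))` and `eta_max` the maximum
#' angular fiber concentration. The unbound fraction is fixed by protein
#' conservation,
#' \deqn{\hat N_u + \int \hat\eta(\phi;\hat N_u)\,\hat n(\phi)\,d\phi = 1,}
#' a monotone scalar equation solved by bracketed root finding on
#' `(0, 1)`; the self-consistency residual is checked against `tol`.
#' (Without the cap the equation is linear in `N_u` and the solve is
#' exact.)
#'
#' @param strain_of_phi Numeric vector of nominal fiber strains on the
#'   angular grid (length `n_angular`), or a function of `phi`.
#' @param rate_of_phi Numeric vector of fiber strain rates on the grid, or a
#'   function of `phi`.
#' @param p An [sf_params()] object.
#' @param tol Tolerance for the conservation residual check.
#' @return An object of class `"sf_state"`: list with `phi_grid`, `eta_hat`,
#'   `n_hat`, `sigma`, `N_b`, `N_u`.
#' @examples
#' p <- sf_params()
#' s <- sf_steady_state(rep(0, p$n_angular), rep(0, p$n_angular), p)
#' s$N_b + s$N_u  # exactly 1
#' @export
sf_steady_state <- function(strain_of_phi, rate_of_phi, p, tol = 1e-10) {
  stopifnot(inherits(p, "sf_params"))
  phi <- phi_grid(p$n_angular)
  if (is.function(strain_of_phi)) strain_of_phi <- strain_of_phi(phi)
  if (is.function(rate_of_phi)) rate_of_phi <- rate_of_phi(phi)
  if (length(strain_of_phi) != length(phi) || length(rate_of_phi) != length(phi))
    stop("strain/rate maps must be defined on the full angular grid")
  n_hat <- steady_units(strain_of_phi, p)
  sigma <- p$sigma_max * hill_factor(rate_of_phi, p)
  chi <- (p$omega * sigma + p$mu_u0 - p$mu_b0) * n_hat / p$kT
  ex <- exp(chi)
  if (any(!is.finite(ex)))
    stop("stress-fiber self-consistency failed: non-finite polymerization integral")
  # conservation gap; pi * mean is the plain angular integral
  gap <- function(Nu) Nu + pi * mean(pmin(p$eta_max, (Nu / pi) * ex) * n_hat) - 1
  if (is.infinite(p$eta_max)) {
    N_u <- 1 / (1 + mean(ex * n_hat))
  } else {
    N_u <- stats::uniroot(gap, c(1e-300, 1), tol = 1e-15)$root
  }
  eta_hat <- pmin(p$eta_max, (N_u / pi) * ex)
  resid <- abs(gap(N_u))
  if (resid > tol)
    stop(sprintf("self-consistency residual %.3g exceeds tolerance %.3g", resid, tol))
  structure(list(phi_grid = phi, eta_hat = eta_hat, n_hat = n_hat,
                 sigma = sigma, N_b = 1 - N_u, N_u = N_u),
            class = "sf_state")
}

#' @export
print.sf_state <- function(x, ...) {
  cat(sprintf("<sf_state> %d angular bins; N_b = %.4f, N_u = %.4f; peak eta*n at phi = %.1f deg\n",
              length(x$phi_grid), x$N_b, x$N_u,
              x$phi_grid[which.max(x$eta_hat * x$n_hat)] * 180 / pi))
  invisible(x)
}

#' Cytoskeletal free energy of a stress-fiber state
#'
#' Combines the enthalpy of the bound functional units (each unit carries
#' the chemical potential `mu_b(phi) = mu_b0 - omega * sigma(phi)`, lowered
#' by the tensile stress-work, and a fiber at angle `phi` holds
#' `n_hat(phi)` units), the unbound-packet energy, and the ideal mixing
#' entropy:
#' \deqn{H_{cyto} = N_T\Big[\int\!\hat\eta\hat n^2\,\mu_b\,d\phi
#'   + \hat N_u \mu_{u0}
#'   + kT\big(\hat N_u\ln\hat N_u + \int\!\hat\eta\hat n
#'     \ln(\hat\eta\hat n)\,d\phi\big)\Big],}
#' with angular integrals over \eqn{(-\pi/2, \pi/2]} so that
#' \eqn{\int\hat\eta\hat n\,d\phi = \hat N_b}. This enthalpy is the
#' variational partner of the Boltzmann closure for `eta_hat` in
#' [sf_steady_state()] (for `mu_u0 = 0` the returned state minimizes
#' `H_cyto` under protein conservation). Polymerization under high tensile
#' stress (isometric fibers) lowers `H_cyto` and the gain grows with fiber
#' stretch, which is what drives cell spreading and elongation;
#' contractile strain rates reduce `sigma` through the Hill relation and
#' raise `H_cyto`.
#'
#' @param s An `"sf_state"` from [sf_steady_state()].
#' @param p An [sf_params()] object.
#' @return Scalar free energy (energy units of `n_T * kT`).
#' @export
cyto_free_energy <- function(s, p) {
  stopifnot(inherits(s, "sf_state"), inherits(p, "sf_params"))
  y <- s$eta_hat * s$n_hat
  mu_b <- p$mu_b0 - p$omega * s$sigma
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  # plain angular integrals: int dphi = pi * mean on the uniform grid
  p$n_T * (p$mu_ref + pi * mean(y * s$n_hat * mu_b) + s$N_u * p$mu_u0 +
             p$kT * (xlogx(s$N_u) + pi * mean(xlogx(y))))
}
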