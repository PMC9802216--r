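#' Substrate principal strains and strain rates
#'
#' Evaluates the imposed biaxial protocol
#' \eqn{\varepsilon_1(t) = \varepsilon_{mean} + (\varepsilon_{amp}/2)\sin(2\pi f t)},
#' \eqn{\varepsilon_2(t) = -r\,\varepsilon_1(t)}, and their exact analytic
#' time derivatives.
#'
#' @param t Time in seconds (vectorized, >= 0).
#' @param load A [cyclic_load()] object.
#' @return A list with numeric components `eps1`, `eps2`, `deps1`, `deps2`.
#' @export
substrate_strain <- function(t, load) {
  stopifnot(inherits(load, "cyclic_load"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  w <- 2 * pi * load$f
  eps1 <- load$eps_mean + (load$eps_amp / 2) * sin(w * t)
  deps1 <- (load$eps_amp / 2) * w * cos(w * t)
  list(eps1 = eps1, eps2 = -load$r * eps1,
       deps1 = deps1, deps2 = -load$r * deps1)
}

#' Fiber strain and strain rate for a microstate under cyclic load
#'
#' The fiber nominal strain follows from the homogeneous cell deformation:
#' a fiber observed at angle `phi` (relative to the major axis, current
#' configuration) is the image of the reference direction `phi_R` with
#' `tan(phi_R) = (a1/a2) tan(phi)`, and its stretch is
#' \deqn{\lambda_f = \sqrt{\hat a_1^2 \cos^2\phi_R + \hat a_2^2 \sin^2\phi_R},}
#' so `eps_nom = lambda_f - 1`. Because the cell stays adhered within a
#' loading period, the fiber strain *rate* equals the substrate strain rate
#' resolved (small-strain) onto the fiber's global direction
#' `delta = phi + theta`:
#' \deqn{\dot\varepsilon_f = \dot\varepsilon_1\cos^2\delta + \dot\varepsilon_2\sin^2\delta.}
#'
#' @param m A `"microstate"` object.
#' @param load A [cyclic_load()] object.
#' @param t Time (s, scalar).
#' @param phi Fiber angle(s) relative to the ellipse major axis (rad).
#' @return A list with `eps_nom` and `eps_rate` (same length as `phi`).
#' @export
fiber_kinematics <- function(m, load, t, phi) {
  stopifnot(inherits(m, "microstate"), inherits(load, "cyclic_load"))
  eps_nom <- fiber_strain(m$a1_hat, m$a2_hat, phi)
  s <- substrate_strain(t, load)
  delta <- phi + m$theta
  cd2 <- cos(delta)^2
  list(eps_nom = eps_nom,
       eps_rate = s$deps1 * cd2 + s$deps2 * (1 - cd2))
}

# Nominal fiber strain at current angle phi for principal stretches a1, a2.
fiber_strain <- function(a1_hat, a2_hat, phi) {
  psi <- atan2(a1_hat * sin(phi), a2_hat * cos(phi)) # reference direction
  sqrt(a1_hat^2 * cos(psi)^2 + a2_hat^2 * sin(psi)^2) - 1
}
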