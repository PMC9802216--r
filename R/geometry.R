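#' Ellipse coefficients from semi-axes and orientation
#'
#' A morphological microstate is an ellipse whose boundary satisfies
#' \deqn{h \hat x_1^2 + k \hat x_1 \hat x_2 + l \hat x_2^2 = 1,}
#' with coordinates normalized by the reference radius `R0`. The
#' nondimensional coefficients are
#' \deqn{h = \cos^2\theta/\hat a_1^2 + \sin^2\theta/\hat a_2^2,\quad
#'       k = (1/\hat a_1^2 - 1/\hat a_2^2)\sin 2\theta,\quad
#'       l = \cos^2\theta/\hat a_2^2 + \sin^2\theta/\hat a_1^2,}
#' where `a1_hat >= a2_hat > 0` are the normalized semi-major/minor axes and
#' `theta` the orientation of the major axis to the x1 (straining) axis.
#'
#' @param a1_hat,a2_hat Normalized semi-axes, `a1_hat >= a2_hat > 0`.
#'   Vectorized.
#' @param theta Orientation in radians. Vectorized.
#' @return A list with numeric components `h`, `k`, `l`.
#' @seealso [geometry_from_coeffs()] for the inverse map.
#' @examples
#' coeffs_from_geometry(2, 1, 0)  # h = 0.25, k = 0, l = 1
#' @export
coeffs_from_geometry <- function(a1_hat, a2_hat, theta) {
  if (any(!is.finite(a1_hat)) || any(!is.finite(a2_hat)) || any(!is.finite(theta)))
    stop("non-finite geometry input")
  if (any(a1_hat <= 0) || any(a2_hat <= 0)) stop("semi-axes must be positive")
  if (any(a2_hat > a1_hat * (1 + 1e-12))) stop("a1_hat must be >= a2_hat")
  ia1 <- 1 / a1_hat^2
  ia2 <- 1 / a2_hat^2
  c2 <- cos(theta)^2
  s2 <- sin(theta)^2
  list(h = c2 * ia1 + s2 * ia2,
       k = (ia1 - ia2) * sin(2 * theta),
       l = c2 * ia2 + s2 * ia1)
}

#' Semi-axes and orientation from ellipse coefficients
#'
#' Inverts the coefficient map by diagonalizing the quadratic form
#' `[[h, k/2], [k/2, l]]`: the semi-axes are the inverse square roots of its
#' eigenvalues and `theta` is the direction of the minor-eigenvalue
#' eigenvector (the major axis), wrapped to `[0, pi)`. For a 2x2 symmetric
#' form this has the closed form `theta = atan2(-k, l - h)/2`.
#'
#' For (numerically) circular states the orientation is undefined; the
#' deterministic tie-break `theta = 0` is used and flagged.
#'
#' @param h,k,l Ellipse coefficients (vectorized).
#' @param circle_tol Relative eigenvalue gap below which the state is
#'   treated as circular.
#' @return A list with components `a1_hat`, `a2_hat`, `theta`
#'   (in `[0, pi)`), and logical `is_circular`.
#' @examples
#' geometry_from_coeffs(0.25, 0, 1)  # a1 = 2, a2 = 1, theta = 0
#' @export
geometry_from_coeffs <- function(h, k, l, circle_tol = 1e-12) {
  if (any(!is.finite(h)) || any(!is.finite(k)) || any(!is.finite(l)))
    stop("non-finite coefficients")
  disc <- 4 * h * l - k^2
  if (any(disc <= 0) || any(h <= 0) || any(l <= 0))
    stop("invalid ellipse: need h > 0, l > 0 and 4hl - k^2 > 0")
  # eigenvalues of [[h, k/2], [k/2, l]]
  s <- (h + l) / 2
  q <- sqrt(((h - l) / 2)^2 + (k / 2)^2)
  lam_min <- s - q
  lam_max <- s + q
  is_circ <- q <= circle_tol * pmax(s, 1)
  theta <- 0.5 * atan2(-k, l - h)
  theta <- ifelse(is_circ, 0, theta %% pi)
  list(a1_hat = 1 / sqrt(lam_min),
       a2_hat = 1 / sqrt(lam_max),
       theta = theta,
       is_circular = is_circ)
}

#' Construct a morphological microstate
#'
#' Stores the coefficients `(h, k, l)` together with the derived geometry:
#' normalized semi-axes, orientation, normalized area
#' `A_hat = a1_hat * a2_hat = 1/sqrt(hl - k^2/4)` and aspect ratio
#' `As = a1_hat/a2_hat >= 1`.
#'
#' @param h,k,l Ellipse coefficients (scalars).
#' @return An object of class `"microstate"`.
#' @export
microstate <- function(h, k, l) {
  g <- geometry_from_coeffs(h, k, l)
  structure(list(h = h, k = k, l = l,
                 a1_hat = g$a1_hat, a2_hat = g$a2_hat, theta = g$theta,
                 is_circular = g$is_circular,
                 A_hat = g$a1_hat * g$a2_hat, As = g$a1_hat / g$a2_hat),
            class = "microstate")
}

#' @export
print.microstate <- function(x, ...) {
  cat(sprintf("<microstate> (h,k,l) = (%.4g, %.4g, %.4g); a1 = %.4g, a2 = %.4g, theta = %.4g rad\n  A_hat = %.4g, As = %.4g%s\n",
              x$h, x$k, x$l, x$a1_hat, x$a2_hat, x$theta, x$A_hat, x$As,
              if (x$is_circular) " (circular)" else ""))
  invisible(x)
}

#' Normalized area and aspect ratio of a microstate
#'
#' @param m A `"microstate"` object.
#' @return Named numeric vector with `A_hat` and `As`.
#' @export
area_aspect <- function(m) {
  stopifnot(inherits(m, "microstate"))
  c(A_hat = m$A_hat, As = m$As)
}

# Vectorized validity test for coefficient triples: positive-definite form
# whose semi-axes fall inside [a_min, a_max].
valid_coeffs <- function(h, k, l, a_min = 0.3, a_max = 4) {
  ok <- h > 0 & l > 0 & (4 * h * l - k^2) > 0
  a1 <- rep(NA_real_, length(h))
  a2 <- rep(NA_real_, length(h))
  if (any(ok)) {
    s <- (h[ok] + l[ok]) / 2
    q <- sqrt(((h[ok] - l[ok]) / 2)^2 + (k[ok] / 2)^2)
    a1[ok] <- 1 / sqrt(s - q)
    a2[ok] <- 1 / sqrt(s + q)
  }
  ok & !is.na(a1) & a1 <= a_max & a2 >= a_min
}
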