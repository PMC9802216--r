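#' Cyclic substrate strain protocol
#'
#' Defines the biaxial cyclic straining of the substrate. The principal
#' substrate strain along x1 is
#' \deqn{\varepsilon_1(t) = \varepsilon_{mean} + (\varepsilon_{amp}/2)\sin(2\pi f t),}
#' and the transverse principal strain is \eqn{\varepsilon_2 = -r\,\varepsilon_1},
#' where \eqn{r} measures the biaxiality of the protocol (\eqn{r = 0} is
#' uniaxial straining, \eqn{r = 1} is pure shear-like biaxial straining).
#' `f = 0` encodes a static (unstrained) substrate.
#'
#' In the stiff-substrate limit modelled here the equilibrium statistics are
#' independent of `eps_mean` (only strain *rates* enter the cytoskeletal
#' response and only the cell's own morphology sets fiber strain), so the
#' default mean strain is zero.
#'
#' @param eps_amp Peak-to-peak strain amplitude (dimensionless, >= 0).
#' @param f Loading frequency in Hz (>= 0; 0 means no cyclic strain).
#' @param r Biaxiality ratio in `[0, 1]`.
#' @param eps_mean Mean strain (dimensionless).
#' @return An object of class `"cyclic_load"`: a list with the fields above
#'   plus the derived period `T_p = 1/f` (seconds, `Inf` for `f = 0`).
#' @examples
#' load <- cyclic_load(eps_amp = 0.1, f = 1, r = 0)
#' substrate_strain(0, load)
#' @export
cyclic_load <- function(eps_amp = 0.1, f = 1, r = 0, eps_mean = 0) {
  stopifnot(is.numeric(eps_amp), length(eps_amp) == 1L, is.finite(eps_amp),
            is.numeric(f), length(f) == 1L, is.finite(f),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(eps_mean), length(eps_mean) == 1L, is.finite(eps_mean))
  if (eps_amp < 0) stop("eps_amp must be >= 0")
  if (f < 0) stop("f must be >= 0")
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  structure(list(eps_amp = eps_amp, f = f, r = r, eps_mean = eps_mean,
                 T_p = if (f > 0) 1 / f else Inf),
            class = "cyclic_load")
}

#' @export
print.cyclic_load <- function(x, ...) {
  if (x$f == 0 || x$eps_amp == 0) {
    cat("<cyclic_load> static substrate (no cyclic strain)\n")
  } else {
    cat(sprintf("<cyclic_load> eps_amp = %g, f = %g Hz, r = %g, eps_mean = %g (T_p = %g s)\n",
                x$eps_amp, x$f, x$r, x$eps_mean, x$T_p))
  }
  invisible(x)
}

#' Stress-fiber model parameters
#'
#' Parameters of the steady-state stress-fiber (SF) thermodynamics. Defaults
#' are given in a nondimensional unit system: energies are measured in units
#' of `n_T * kT` (with `kT = 1` and `n_T = 1`) and stresses in units such
#' that `omega * sigma_max / kT` is the dimensionless isometric stress-work
#' exponent. Only such dimensionless groups enter any reported observable,
#' so this loses no generality; all fields may be given in physical units
#' provided they are mutually consistent.
#'
#' The default values were calibrated once so that the static free-energy
#' landscape has its minimum near `(a1/R0, a2/R0) = (1.85, 0.72)` and the
#' cyclic (1 Hz, amplitude 0.1) landscape at 90 degrees near `(1.9, 0.68)`;
#' see the methods vignette.
#'
#' @param sigma_max Isometric SF stress scale (stress units).
#' @param eps_rate_0 Reference strain rate of the Hill relation (1/s).
#' @param k_v Hill rate-sensitivity factor (dimensionless).
#' @param eps_ss Intrinsic steady-state functional-unit strain (dimensionless).
#' @param mu_b0 Reference chemical potential of a bound SF packet (energy).
#' @param mu_u0 Reference chemical potential of an unbound packet (energy).
#' @param omega Stress-work volume factor (volume units).
#' @param kT Thermal energy scale (energy).
#' @param n_T Total number of SF protein packets (sets the energy scale of
#'   `H_cyto`).
#' @param eta_max Maximum angular SF concentration (cap on `eta_hat`;
#'   `Inf` disables the cap). Saturation of the fiber concentration along
#'   the most-stretched direction is what limits cell elongation.
#' @param mu_ref Reference chemical free energy of the whole SF protein
#'   reservoir (energy). Because the total packet concentration is
#'   conserved, this term is identical for every morphology and for the
#'   suspended cell; it only sets the absolute scale of `H_s` (and hence
#'   the magnitude of `beta_hat = beta |H_s|`), not any equilibrium
#'   weight or landscape shape.
#' @param n_angular Number of SF angular bins over `(-pi/2, pi/2]`
#'   (even integer, >= 8).
#' @return An object of class `"sf_params"`.
#' @export
sf_params <- function(sigma_max = 9.5,
                      eps_rate_0 = 0.1,
                      k_v = 1.6,
                      eps_ss = 0.35,
                      mu_b0 = 0,
                      mu_u0 = 0,
                      omega = 1,
                      kT = 1,
                      n_T = 1,
                      eta_max = 0.72,
                      mu_ref = -10.553,
                      n_angular = 36L) {
  p <- list(sigma_max = sigma_max, eps_rate_0 = eps_rate_0, k_v = k_v,
            eps_ss = eps_ss, mu_b0 = mu_b0, mu_u0 = mu_u0, omega = omega,
            kT = kT, n_T = n_T, eta_max = eta_max, mu_ref = mu_ref,
            n_angular = as.integer(n_angular))
  for (f in c("sigma_max", "eps_rate_0", "k_v", "eps_ss", "mu_b0", "mu_u0",
              "omega", "kT", "n_T", "mu_ref")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("sf_params field '", f, "' must be a finite scalar")
  }
  if (p$sigma_max <= 0) stop("sigma_max must be > 0")
  if (p$eps_rate_0 <= 0) stop("eps_rate_0 must be > 0")
  if (p$k_v <= 0) stop("k_v must be > 0")
  if (p$kT <= 0) stop("kT must be > 0")
  if (p$eps_ss <= -1) stop("eps_ss must be > -1")
  if (!is.numeric(p$eta_max) || length(p$eta_max) != 1L || p$eta_max <= 0 ||
      is.na(p$eta_max))
    stop("eta_max must be a positive scalar (possibly Inf)")
  if (p$n_angular < 8L || p$n_angular %% 2L != 0L)
    stop("n_angular must be an even integer >= 8")
  class(p) <- "sf_params"
  p
}

#' @export
print.sf_params <- function(x, ...) {
  cat(sprintf(paste0("<sf_params> sigma_max = %g, eps_rate_0 = %g /s, k_v = %g, ",
                     "eps_ss = %g,\n  mu_b0 = %g, mu_u0 = %g, omega = %g, kT = %g, ",
                     "n_T = %g,\n  eta_max = %g, mu_ref = %g, n_angular = %d\n"),
              x$sigma_max, x$eps_rate_0, x$k_v, x$eps_ss, x$mu_b0, x$mu_u0,
              x$omega, x$kT, x$n_T, x$eta_max, x$mu_ref, x$n_angular))
  invisible(x)
}

#' Cell elasticity and geometry parameters
#'
#' Passive-elasticity and reference-geometry parameters of the cell. The
#' undeformed (elastic resting) state is a circle of radius `R0` containing
#' a concentric circular nucleus of radius `R_N`; the nucleus deforms
#' affinely with the (spatially uniform) cell stretch. Moduli are areal
#' strain-energy densities (energy per unit reference area); with the
#' default nondimensional unit system they are in units of `n_T*kT/R0^2`.
#'
#' The shear modulus of the cytoplasm must be below its bulk modulus: cells
#' elongate because deviatoric deformation is elastically cheaper than
#' areal growth.
#'
#' @param R0 Reference cell radius (length; 1 in nondimensional units).
#' @param R_N Nucleus radius (length, < `R0`).
#' @param mu_cyto,kappa_cyto Cytoplasm shear/bulk moduli.
#' @param mu_nuc,kappa_nuc Nucleus shear/bulk moduli.
#' @param suspension_radius_factor Radius of the cell in suspension as a
#'   fraction of `R0` (default 0.96, so the suspended normalized area is
#'   0.96^2 = 0.9216).
#' @param suspension_stress_factor Fraction of the isometric stress
#'   `sigma_max` that stress fibers in the suspended (unadhered) cell can
#'   sustain by contracting against the cell's own cortex rather than a
#'   substrate, in `[0, 1]`. Sets how favorable the suspension reference
#'   state is and therefore the level of the homeostatic target `H_s`.
#' @param H_s Suspension free energy (energy). Computed from the model by
#'   [suspension_energy()] when `NULL` (the default).
#' @return An object of class `"cell_params"`.
#' @export
cell_params <- function(R0 = 1,
                        R_N = 0.5,
                        mu_cyto = 0.68,
                        kappa_cyto = 2.8,
                        mu_nuc = 1.36,
                        kappa_nuc = 5.6,
                        suspension_radius_factor = 0.96,
                        suspension_stress_factor = 0.45,
                        H_s = NULL) {
  p <- list(R0 = R0, R_N = R_N, mu_cyto = mu_cyto, kappa_cyto = kappa_cyto,
            mu_nuc = mu_nuc, kappa_nuc = kappa_nuc,
            suspension_radius_factor = suspension_radius_factor,
            suspension_stress_factor = suspension_stress_factor, H_s = H_s)
  for (f in c("R0", "R_N", "mu_cyto", "kappa_cyto", "mu_nuc", "kappa_nuc",
              "suspension_radius_factor")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("cell_params field '", f, "' must be a positive finite scalar")
  }
  if (p$R_N >= p$R0) stop("R_N must be smaller than R0")
  if (!is.numeric(p$suspension_stress_factor) ||
      p$suspension_stress_factor < 0 || p$suspension_stress_factor > 1)
    stop("suspension_stress_factor must lie in [0, 1]")
  if (p$mu_cyto >= p$kappa_cyto)
    stop("mu_cyto must be smaller than kappa_cyto")
  if (!is.null(H_s) && (!is.numeric(H_s) || length(H_s) != 1L || !is.finite(H_s)))
    stop("H_s must be NULL or a finite scalar")
  class(p) <- "cell_params"
  p
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(paste0("<cell_params> R0 = %g, R_N = %g, mu_cyto = %g, kappa_cyto = %g,\n",
                     "  mu_nuc = %g, kappa_nuc = %g, suspension factor = %g, H_s = %s\n"),
              x$R0, x$R_N, x$mu_cyto, x$kappa_cyto, x$mu_nuc, x$kappa_nuc,
              x$suspension_radius_factor,
              if (is.null(x$H_s)) "(unset)" else format(x$H_s)))
  invisible(x)
}

# Angular grid over (-pi/2, pi/2]; uniform, periodic with period pi.
# (1/pi) * integral over the grid of any periodic function equals its mean.
phi_grid <- function(n_angular) {
  -pi / 2 + (seq_len(n_angular)) * pi / n_angular
}
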