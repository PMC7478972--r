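#' Perrin friction and diffusion coefficients of a prolate spheroid
#'
#' Closed-form Perrin factors for a prolate spheroid of semi-major axis `a`
#' and semi-minor axis `b` in a fluid of viscosity `eta`. Translational
#' friction is returned along and perpendicular to the symmetry axis, together
#' with the orientation-averaged coefficient, and rotational friction about
#' the short axes (the mode that randomizes the swimming direction).
#' Diffusivities follow from the Einstein relation D = kT / friction.
#'
#' Units: lengths in um, viscosity in mPa s (= cP), friction in pN s / um
#' (translational) and pN s um (rotational), diffusivities in um^2/s and 1/s.
#'
#' @param semi_major,semi_minor spheroid semi-axes a >= b > 0 (um).
#' @param viscosity dynamic viscosity (mPa s). Default 1.82, the measured
#'   viscosity of the haloarchaeal growth medium.
#' @param temperature absolute temperature (K) for the Einstein relation.
#' @return A list of class `perrin_friction` with elements `gamma_par`,
#'   `gamma_perp`, `gamma_avg`, `gamma_rot`, `D_par`, `D_perp`, `D_avg`,
#'   `D_r`, plus the inputs.
#' @examples
#' perrin_friction(2.25, 0.35)          # effective flagellated archaeal cell
#' perrin_friction(1, 1, viscosity = 1) # sphere: gamma_avg = 6*pi*eta*a
#' @export
perrin_friction <- function(semi_major, semi_minor, viscosity = 1.82,
                            temperature = 298) {
  a <- semi_major; b <- semi_minor
  if (!(b > 0) || a < b) stop("need semi_major >= semi_minor > 0")
  if (!(viscosity > 0)) stop("viscosity must be positive")
  eta <- viscosity * 1e-3  # mPa s -> pN s / um^2

  if ((a - b) / a < 1e-8) {
    # sphere limit (the general expressions are 0/0 here)
    chi <- 2 / a
    alpha_a <- alpha_b <- (2 / 3) / a^3
  } else {
    xi <- sqrt(a^2 - b^2)
    chi <- (2 / xi) * log((a + xi) / b)
    alpha_a <- (chi - 2 / a) / xi^2
    alpha_b <- (chi - a^2 * alpha_a) / (2 * b^2)
  }
  gamma_par <- 16 * pi * eta / (chi + a^2 * alpha_a)
  gamma_perp <- 16 * pi * eta / (chi + b^2 * alpha_b)
  gamma_rot <- 16 * pi * eta * (a^2 + b^2) / (3 * (a^2 * alpha_a + b^2 * alpha_b))

  kT <- .kB_pN_um * temperature
  D_par <- kT / gamma_par
  D_perp <- kT / gamma_perp
  D_avg <- (D_par + 2 * D_perp) / 3
  structure(list(
    gamma_par = gamma_par, gamma_perp = gamma_perp,
    gamma_avg = kT / D_avg, gamma_rot = gamma_rot,
    D_par = D_par, D_perp = D_perp, D_avg = D_avg,
    D_r = kT / gamma_rot,
    semi_major = a, semi_minor = b,
    viscosity = viscosity, temperature = temperature),
    class = "perrin_friction")
}

#' @export
print.perrin_friction <- function(x, ...) {
  cat(sprintf(
    "<perrin_friction: a = %.2f um, b = %.2f um, eta = %.2f mPa s>\n",
    x$semi_major, x$semi_minor, x$viscosity))
  cat(sprintf("  gamma_avg = %.4g pN s/um   D_avg = %.4g um^2/s   D_r = %.4g 1/s\n",
              x$gamma_avg, x$D_avg, x$D_r))
  invisible(x)
}
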