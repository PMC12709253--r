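#' Machin number of an oscillating filament
#'
#' The dimensionless ratio of hydrodynamic to bending forces for a filament
#' driven at frequency f with wavelength \eqn{\lambda}:
#' \deqn{Ma = \frac{f\,\xi_\perp\,\lambda^4}{8\pi^3\kappa}.}
#' \eqn{Ma \ll 1} means the beat is bending-dominated (the short-cilium
#' regime in which analytic traveling-wave solutions exist). Drag and
#' stiffness values are user-supplied; none are hardcoded.
#'
#' @param frequency_hz Beat frequency f (Hz).
#' @param lambda_um Wavelength \eqn{\lambda} (um).
#' @param xi_perp Perpendicular drag coefficient \eqn{\xi_\perp}
#'   (pN s/um^2).
#' @param kappa Flexural rigidity \eqn{\kappa} (pN um^2).
#' @return Dimensionless Machin number.
#' @examples
#' machin_number(1, 1, 1, 1)  # 1 / (8 pi^3)
#' @export
machin_number <- function(frequency_hz, lambda_um, xi_perp, kappa) {
  if (any(kappa <= 0)) abort("`kappa` must be positive.",
                             class = "ciliawave_parameter_error")
  frequency_hz * xi_perp * lambda_um^4 / (8 * pi^3 * kappa)
}

#' Propulsive force per unit length of a small-amplitude sinusoidal beat
#'
#' For a straight filament undergoing a small-amplitude sinusoidal beat of
#' transverse amplitude \eqn{y_0}, frequency f and wavelength
#' \eqn{\lambda}, resistive-force theory gives
#' \deqn{F/L = 2\pi^2 (\xi_\perp - \xi_\parallel)\, f y_0^2 / \lambda.}
#' Thrust requires drag anisotropy (\eqn{\xi_\perp > \xi_\parallel}) and
#' grows as the wavelength shortens.
#'
#' @param frequency_hz Beat frequency f (Hz).
#' @param amplitude_um Transverse amplitude \eqn{y_0} (um).
#' @param lambda_um Wavelength \eqn{\lambda} (um).
#' @param xi_perp,xi_par Perpendicular and parallel drag coefficients
#'   (pN s/um^2).
#' @return Propulsive force per unit length (pN/um).
#' @examples
#' propulsive_force_per_length(1, 1, 1, 1, 0)  # 2 pi^2
#' @export
propulsive_force_per_length <- function(frequency_hz, amplitude_um,
                                        lambda_um, xi_perp, xi_par) {
  if (any(lambda_um <= 0)) abort("`lambda_um` must be positive.",
                                 class = "ciliawave_parameter_error")
  2 * pi^2 * (xi_perp - xi_par) * frequency_hz * amplitude_um^2 / lambda_um
}

#' Swimming speed from propulsive force
#'
#' At low Reynolds number the swimming speed of a filament of length L
#' propelled by total force F against parallel drag \eqn{\xi_\parallel} is
#' \deqn{v = F / (L\,\xi_\parallel).}
#'
#' @param force_pn Total propulsive force F (pN).
#' @param length_um Filament length L (um).
#' @param xi_par Parallel drag coefficient (pN s/um^2).
#' @return Swimming speed (um/s).
#' @examples
#' swimming_speed(10, 10, 0.5)  # 2 um/s
#' @export
swimming_speed <- function(force_pn, length_um, xi_par) {
  if (any(length_um <= 0) || any(xi_par <= 0)) {
    abort("`length_um` and `xi_par` must be positive.",
          class = "ciliawave_parameter_error")
  }
  force_pn / (length_um * xi_par)
}
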