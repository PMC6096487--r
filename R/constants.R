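# Physical constants (CODATA 2018), frozen here and used everywhere.
# Units: SI unless noted.

.const <- list(
  h      = 6.62607015e-34,   # Planck constant, J s (exact)
  c      = 299792458,        # speed of light, m s^-1 (exact)
  e      = 1.602176634e-19,  # elementary charge, C (exact)
  m0     = 9.1093837015e-31, # electron rest mass, kg
  hc_keV_A = 12.39841984     # h*c/e in keV Angstrom
)

#' Relativistic electron wavelength from accelerating voltage
#'
#' Computes the de Broglie wavelength of electrons accelerated through a
#' potential of \code{accel_voltage} kilovolts, including the relativistic
#' correction:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}}
#' At 200 kV this gives 0.02508 Angstrom, roughly 40 times shorter than a
#' typical X-ray wavelength, which is what makes the Ewald sphere in electron
#' diffraction nearly flat.
#'
#' @param accel_voltage Accelerating voltage in kV. Must be positive.
#' @return Wavelength in Angstrom.
#' @examples
#' wavelength_from_kv(200)  # ~0.02508
#' @export
wavelength_from_kv <- function(accel_voltage) {
  if (!is.numeric(accel_voltage) || any(accel_voltage <= 0))
    stop("edgeom_invalid_argument: accel_voltage must be > 0 kV")
  V <- accel_voltage * 1e3
  with(.const, {
    p2 <- 2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2))
    h / sqrt(p2) * 1e10
  })
}

#' X-ray wavelength from photon energy
#'
#' \eqn{\lambda = hc/(eE)}; with E in keV this is approximately
#' 12.398420 / E Angstrom. 12 keV X-rays have a wavelength of 1.0332 Angstrom.
#'
#' @param energy Photon energy in keV. Must be positive.
#' @return Wavelength in Angstrom.
#' @examples
#' xray_wavelength_from_kev(12)  # ~1.0332
#' @export
xray_wavelength_from_kev <- function(energy) {
  if (!is.numeric(energy) || any(energy <= 0))
    stop("edgeom_invalid_argument: energy must be > 0 keV")
  .const$hc_keV_A / energy
}
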