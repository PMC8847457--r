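#' Theoretical axial resolution of an OCT source
#'
#' Coherence-length full width at half maximum of a Gaussian source spectrum,
#' \deqn{\Delta z = \frac{2\ln 2}{\pi}\,\frac{\lambda_0^2}{\Delta\lambda},}
#' where \eqn{\lambda_0} is the centre wavelength and \eqn{\Delta\lambda} the
#' spectral bandwidth (both in nm). This value is also used as the default
#' axial point-spread-function FWHM of the retinal phantom.
#'
#' @param center_wavelength_nm Source centre wavelength in nm.
#' @param bandwidth_nm Source spectral bandwidth (FWHM) in nm.
#' @return Axial resolution in micrometres.
#' @examples
#' axial_resolution(810, 100)  # ~2.9 um
#' @export
axial_resolution <- function(center_wavelength_nm, bandwidth_nm) {
  if (!is.numeric(center_wavelength_nm) || !is.numeric(bandwidth_nm) ||
      length(center_wavelength_nm) != 1L || length(bandwidth_nm) != 1L ||
      !is.finite(center_wavelength_nm) || is.na(bandwidth_nm) ||
      center_wavelength_nm <= 0 || bandwidth_nm <= 0)
    retorg_error("parameter",
                 "axial_resolution() needs positive wavelength and bandwidth")
  (2 * log(2) / pi) * center_wavelength_nm^2 / bandwidth_nm / 1000
}

#' Frame period of a high-speed acquisition
#'
#' @param frame_rate_hz Acquisition frame rate in frames per second.
#' @return Frame period in milliseconds (temporal resolution of the M-scan
#'   source recording; 16 fps gives 62.5 ms).
#' @export
frame_period_ms <- function(frame_rate_hz) {
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    retorg_error("parameter", "frame rate must be a positive number")
  1000 / frame_rate_hz
}
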