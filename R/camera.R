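#' EMCCD camera model
#'
#' Bundles the acquisition parameters needed to convert between raw
#' analog-to-digital counts (ADC), detected photons, physical position and
#' time. Defaults describe the growth-cone regime: 118 nm effective pixels,
#' 200 ms exposure, EM gain 200, and an overall conversion of 13.4 ADC per
#' detected photon (so that a ~500-photon flash integrates to ~6700 ADC).
#'
#' @param pixel_size_nm Effective pixel size on the sample, nanometres.
#' @param exposure_s Exposure time per frame, seconds.
#' @param em_gain Electron-multiplying gain (dimensionless, >= 1).
#' @param adc_per_photon ADC counts per detected photon at the set EM gain.
#' @param offset_adc Camera baseline (dark offset), ADC counts.
#' @param read_noise_adc Standard deviation of Gaussian readout noise, ADC.
#' @return An object of class `smti_camera`.
#' @examples
#' cam <- camera_model()
#' adc_to_photons(6700, cam) # ~500
#' @export
camera_model <- function(pixel_size_nm = 118, exposure_s = 0.2, em_gain = 200,
                         adc_per_photon = 13.4, offset_adc = 100,
                         read_noise_adc = 10) {
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  check_number(exposure_s, "exposure_s", lower = 1e-12)
  check_number(em_gain, "em_gain", lower = 1)
  check_number(adc_per_photon, "adc_per_photon", lower = 1e-12)
  check_number(offset_adc, "offset_adc", lower = 0)
  check_number(read_noise_adc, "read_noise_adc", lower = 0)
  structure(
    list(
      pixel_size_nm = pixel_size_nm, exposure_s = exposure_s,
      em_gain = em_gain, adc_per_photon = adc_per_photon,
      offset_adc = offset_adc, read_noise_adc = read_noise_adc
    ),
    class = "smti_camera"
  )
}

#' @export
print.smti_camera <- function(x, ...) {
  cat(sprintf(
    paste0("<smti_camera> %g nm px, %g s exposure, EM gain %g, ",
           "%g ADC/photon, offset %g, read noise %g ADC\n"),
    x$pixel_size_nm, x$exposure_s, x$em_gain, x$adc_per_photon,
    x$offset_adc, x$read_noise_adc
  ))
  invisible(x)
}

#' Convert integrated ADC counts to detected photons
#'
#' @param adc_sum Background-corrected integrated ADC counts (>= 0).
#' @param camera A [camera_model()].
#' @return Photon count(s), `adc_sum / adc_per_photon`.
#' @export
adc_to_photons <- function(adc_sum, camera) {
  stopifnot(inherits(camera, "smti_camera"))
  if (any(adc_sum < 0, na.rm = TRUE)) {
    abort("`adc_sum` must be non-negative.")
  }
  adc_sum / camera$adc_per_photon
}

#' Convert detected photons to integrated ADC counts
#'
#' Inverse of [adc_to_photons()].
#' @inheritParams adc_to_photons
#' @param photons Photon count(s) (>= 0).
#' @export
photons_to_adc <- function(photons, camera) {
  stopifnot(inherits(camera, "smti_camera"))
  if (any(photons < 0, na.rm = TRUE)) {
    abort("`photons` must be non-negative.")
  }
  photons * camera$adc_per_photon
}

#' Acquisition time of a frame
#'
#' Frames are 0-based; frame `k` is assigned its start time
#' `start_time_s + k * exposure_s`. All modules share this convention.
#'
#' @param frame Integer frame index (0-based), vectorized.
#' @param camera A [camera_model()].
#' @param start_time_s Acquisition start time in seconds.
#' @export
frame_start_time <- function(frame, camera, start_time_s = 0) {
  stopifnot(inherits(camera, "smti_camera"))
  frame_time(frame, camera, start_time_s)
}
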