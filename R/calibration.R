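#' Spatial calibration
#'
#' Maps pixels to microns either from the camera sensor pixel pitch and the
#' objective magnification (projected pixel size = sensor / magnification) or
#' from a directly supplied scale. Exactly one of the two modes must be used.
#'
#' @param microns_per_px Direct scale, micron / pixel.
#' @param sensor_pixel_um Physical sensor pixel size, micron (e.g. 5.2 for
#'   the recommended monochrome CCD).
#' @param magnification Objective magnification (e.g. 4 or 10).
#' @return An object of class `vt_calibration`.
#' @examples
#' microns_per_pixel(calibration(sensor_pixel_um = 5.2, magnification = 4))   # 1.3
#' microns_per_pixel(calibration(sensor_pixel_um = 5.2, magnification = 10))  # 0.52
#' @export
calibration <- function(microns_per_px = NULL, sensor_pixel_um = NULL,
                        magnification = NULL) {
  direct <- !is.null(microns_per_px)
  sensor <- !is.null(sensor_pixel_um) || !is.null(magnification)
  if (direct && sensor) {
    stop_validation("give either `microns_per_px` or sensor_pixel_um + magnification, not both")
  }
  if (!direct && !sensor) {
    stop_validation("calibration required: give `microns_per_px` or sensor_pixel_um + magnification")
  }
  if (direct) {
    check_number(microns_per_px, "microns_per_px", min = 1e-9)
    structure(list(mode = "direct", microns_per_px = microns_per_px),
              class = "vt_calibration")
  } else {
    check_number(sensor_pixel_um, "sensor_pixel_um", min = 1e-9)
    check_number(magnification, "magnification", min = 1e-9)
    structure(list(mode = "sensor", sensor_pixel_um = sensor_pixel_um,
                   magnification = magnification),
              class = "vt_calibration")
  }
}

#' Projected pixel size
#'
#' @param calib A [calibration()].
#' @return Micron per pixel.
#' @export
microns_per_pixel <- function(calib) {
  if (!inherits(calib, "vt_calibration")) {
    stop_validation("`calib` must be created with calibration()")
  }
  if (calib$mode == "direct") calib$microns_per_px
  else calib$sensor_pixel_um / calib$magnification
}

#' Field of view in millimetres
#'
#' @param calib A [calibration()].
#' @param width_px,height_px Frame size in pixels.
#' @return Named numeric vector `c(width_mm, height_mm)`.
#' @export
field_of_view_mm <- function(calib, width_px, height_px) {
  mpp <- microns_per_pixel(calib)
  check_number(width_px, "width_px", min = 0)
  check_number(height_px, "height_px", min = 0)
  c(width_mm = width_px * mpp / 1000, height_mm = height_px * mpp / 1000)
}
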