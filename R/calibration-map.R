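#' Pixel-to-wavelength calibration map
#'
#' A polynomial map from pixel index to wavelength in nm, together with the
#' pixel index bounds it is valid for and the working wavelength range over
#' which absorbance output is trusted. Line-sensor vendors ship per-chip
#' factory polynomials of this form; all coefficients are user-settable.
#'
#' @param coefficients Numeric vector of polynomial coefficients, lowest order
#'   first, mapping pixel index to wavelength in nm.
#' @param pixel_range Integer vector of length 2: inclusive pixel index bounds.
#' @param working_range Numeric vector of length 2: trusted wavelength interval
#'   `(lambda_min, lambda_max)` in nm. Default `c(450, 750)`.
#' @return An object of class `wavelength_calibration`.
#' @examples
#' cal <- wavelength_calibration(c(340, 1.77), pixel_range = c(0, 287))
#' pixel_to_wavelength(cal, 100)
#' @export
wavelength_calibration <- function(coefficients, pixel_range = c(0L, 287L),
                                   working_range = c(450, 750)) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            length(pixel_range) == 2, length(working_range) == 2,
            working_range[1] < working_range[2])
  pixel_range <- as.integer(pixel_range)
  if (pixel_range[1] > pixel_range[2])
    stop("pixel_range must be nondecreasing")
  cal <- structure(
    list(coefficients = as.numeric(coefficients),
         pixel_range = pixel_range,
         working_range = as.numeric(working_range)),
    class = "wavelength_calibration")
  lam <- pixel_to_wavelength(cal, seq(pixel_range[1], pixel_range[2]))
  if (any(diff(lam) <= 0))
    stop("calibration map must be strictly increasing over pixel_range")
  if (working_range[1] < lam[1] || working_range[2] > lam[length(lam)])
    stop("working_range must be contained in the image of the pixel map")
  cal
}

#' Evaluate a calibration map at pixel indices
#'
#' @param cal A [wavelength_calibration()].
#' @param pixel Integer pixel index (vectorised). Must lie within
#'   `cal$pixel_range`.
#' @return Wavelength(s) in nm.
#' @export
pixel_to_wavelength <- function(cal, pixel) {
  stopifnot(inherits(cal, "wavelength_calibration"))
  if (any(pixel < cal$pixel_range[1] | pixel > cal$pixel_range[2]))
    stop("pixel index outside pixel_range [", cal$pixel_range[1], ", ",
         cal$pixel_range[2], "]")
  co <- cal$coefficients
  out <- rep(co[1], length(pixel))
  pw <- rep(1, length(pixel))
  for (k in seq_along(co)[-1]) {
    pw <- pw * pixel
    out <- out + co[k] * pw
  }
  out
}

#' Default factory-style calibration map
#'
#' A fifth-order polynomial over 288 pixels chosen to emulate a visible-range
#' line-sensor chip: coverage from about 340 nm up to the near-infrared chip
#' limit, with a non-linear pixel pitch whose adjacent-pixel step averages
#' about 2.2 nm (roughly 1.9--2.3 nm) across the 450--750 nm working range.
#' Real units carry per-chip factory coefficients; these defaults are a
#' repository choice with the same shape.
#'
#' @param working_range Trusted wavelength interval in nm.
#' @return A [wavelength_calibration()].
#' @export
default_calibration <- function(working_range = c(450, 750)) {
  wavelength_calibration(
    coefficients = c(3.405339326e+02, 1.592646746e+00, 4.934843998e-03,
                     4.787553557e-06, -1.390941612e-07, 2.666241264e-10),
    pixel_range = c(0L, 287L),
    working_range = working_range)
}

#' @export
print.wavelength_calibration <- function(x, ...) {
  lam <- pixel_to_wavelength(x, x$pixel_range)
  cat("<wavelength_calibration>\n")
  cat(sprintf("  pixels %d..%d  ->  %.1f..%.1f nm (degree %d)\n",
              x$pixel_range[1], x$pixel_range[2], lam[1], lam[2],
              length(x$coefficients) - 1L))
  cat(sprintf("  working range: %.0f-%.0f nm\n",
              x$working_range[1], x$working_range[2]))
  invisible(x)
}

# pixels whose mapped wavelength falls inside the working range
working_pixels <- function(cal) {
  px <- seq(cal$pixel_range[1], cal$pixel_range[2])
  lam <- pixel_to_wavelength(cal, px)
  px[lam >= cal$working_range[1] & lam <= cal$working_range[2]]
}
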