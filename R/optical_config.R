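#' Optical configuration of the off-axis holographic microscope
#'
#' Collects the physical constants of the interferometer needed both to
#' synthesize holograms and to interpret recorded ones: the laser
#' wavelength, the object-plane pixel pitch, the refractive index of the
#' culture medium, the carrier tilt between object and reference beams,
#' the sensor geometry and its bit depth.
#'
#' The carrier tilt is expressed as spatial angular frequencies
#' \code{tilt_alpha} (along x) and \code{tilt_beta} (along y) in radians
#' per micrometre at the image plane.  When both are \code{NULL} they are
#' derived from \code{carrier_frac}, the carrier magnitude as a fraction
#' of the Nyquist limit along the image diagonal, and snapped to an exact
#' integer number of DFT bins so that a simulated carrier is leakage-free
#' and demodulation leaves no residual linear phase.  The sign convention
#' (\code{tilt_beta < 0}) places the +1 sidelobe in the upper half of the
#' centred spectrum, which is where \code{\link{locate_sidelobe}} looks,
#' so phase delays (specimen index above the medium) come out positive.
#'
#' @param wavelength Laser wavelength in micrometres (default 0.532).
#' @param pixel_pitch Object-plane pixel pitch in micrometres per pixel.
#' @param n_medium Refractive index of the surrounding medium
#'   (default 1.336, a physiological culture medium).
#' @param image_shape Integer vector \code{c(rows, cols)} of the sensor.
#' @param bit_depth Camera bit depth (default 16).
#' @param carrier_frac Carrier magnitude as a fraction of Nyquist along
#'   the image diagonal, used when tilts are not given (default 1/8).
#' @param tilt_alpha,tilt_beta Carrier spatial angular frequencies in
#'   rad/um along x and y; overrides \code{carrier_frac} when non-NULL.
#' @return An object of class \code{optical_config}.
#' @examples
#' cfg <- optical_config()
#' cfg$tilt_alpha * cfg$pixel_pitch  # well below pi: sidelobe in band
#' @export
optical_config <- function(wavelength = 0.532,
                           pixel_pitch = 0.3,
                           n_medium = 1.336,
                           image_shape = c(512L, 512L),
                           bit_depth = 16L,
                           carrier_frac = 1 / 8,
                           tilt_alpha = NULL,
                           tilt_beta = NULL) {
  stopifnot(wavelength > 0, pixel_pitch > 0, n_medium >= 1,
            length(image_shape) == 2, all(image_shape >= 4),
            bit_depth %in% c(8L, 12L, 14L, 16L))
  image_shape <- as.integer(image_shape)
  if (is.null(tilt_alpha) != is.null(tilt_beta))
    stop("give both tilt_alpha and tilt_beta, or neither")
  if (is.null(tilt_alpha)) {
    tilts <- carrier_tilt(image_shape, pixel_pitch, carrier_frac)
    tilt_alpha <- tilts[["tilt_alpha"]]
    tilt_beta <- tilts[["tilt_beta"]]
  }
  if (sqrt(tilt_alpha^2 + tilt_beta^2) * pixel_pitch >= pi)
    stop("carrier tilt violates the Nyquist bound: ",
         "sqrt(alpha^2 + beta^2) * pixel_pitch must be < pi")
  structure(
    list(wavelength = wavelength, pixel_pitch = pixel_pitch,
         n_medium = n_medium, image_shape = image_shape,
         bit_depth = as.integer(bit_depth),
         tilt_alpha = tilt_alpha, tilt_beta = tilt_beta),
    class = "optical_config")
}

#' Carrier tilt snapped to integer DFT bins
#'
#' Computes carrier spatial angular frequencies along x and y whose
#' magnitude is approximately \code{frac} of the Nyquist limit along the
#' image diagonal, rounded to an exact integer number of DFT bins per
#' axis.  The y component is returned negative (see
#' \code{\link{optical_config}} for the sign convention).
#'
#' @param image_shape Integer \code{c(rows, cols)}.
#' @param pixel_pitch Pixel pitch in micrometres per pixel.
#' @param frac Fraction of the diagonal Nyquist limit.
#' @return Named numeric vector \code{c(tilt_alpha=, tilt_beta=)} in
#'   rad/um.
#' @export
carrier_tilt <- function(image_shape, pixel_pitch, frac = 1 / 8) {
  stopifnot(frac > 0, frac < 1)
  nr <- image_shape[1]; nc <- image_shape[2]
  # per-axis component of a diagonal carrier at frac * Nyquist, in bins
  bins_x <- max(1, round(frac * nc / (2 * sqrt(2))))
  bins_y <- max(1, round(frac * nr / (2 * sqrt(2))))
  c(tilt_alpha = bins_x * 2 * pi / (nc * pixel_pitch),
    tilt_beta = -bins_y * 2 * pi / (nr * pixel_pitch))
}

wavenumber <- function(config) 2 * pi / config$wavelength

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength : %.4g um   (k = %.4g rad/um)\n",
              x$wavelength, 2 * pi / x$wavelength))
  cat(sprintf("  pixel pitch: %.4g um/px, image %d x %d px (%.1f x %.1f um)\n",
              x$pixel_pitch, x$image_shape[1], x$image_shape[2],
              x$image_shape[1] * x$pixel_pitch,
              x$image_shape[2] * x$pixel_pitch))
  cat(sprintf("  n_medium   : %.4f,  bit depth %d\n", x$n_medium, x$bit_depth))
  cat(sprintf("  carrier    : alpha %.4g, beta %.4g rad/um (|f|*pitch = %.3f pi)\n",
              x$tilt_alpha, x$tilt_beta,
              sqrt(x$tilt_alpha^2 + x$tilt_beta^2) * x$pixel_pitch / pi))
  invisible(x)
}
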