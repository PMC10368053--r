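#' Centred Fourier spectrum of an interferogram
#'
#' Discrete Fourier transform of the intensity image with the zero
#' frequency shifted to the array centre (bin \code{floor(n/2)+1} on each
#' axis).  Satisfies Parseval's identity:
#' \code{sum(Mod(S)^2) / N == sum(I^2)}.
#'
#' @param holo An \code{\link{interferogram}} or a plain numeric matrix.
#' @param config Optional \code{\link{optical_config}} when \code{holo}
#'   is a bare matrix.
#' @return Object of class \code{complex_spectrum}: list with complex
#'   matrix \code{values}, per-axis \code{frequency_pitch} (cycles/um per
#'   bin) and the \code{config}.
#' @export
fourier_spectrum <- function(holo, config = NULL) {
  if (inherits(holo, "interferogram")) {
    config <- holo$config
    m <- holo$pixels
  } else {
    m <- holo
  }
  if (!is.matrix(m)) stop("interferogram must be a 2D matrix")
  S <- fftshift2(stats::fft(m))
  fp <- if (!is.null(config))
    1 / (dim(m) * config$pixel_pitch) else 1 / dim(m)
  structure(list(values = S, frequency_pitch = fp, config = config),
            class = "complex_spectrum")
}

#' Locate the off-axis sidelobe in a hologram spectrum
#'
#' Finds the modulation sideband as the magnitude maximum outside a DC
#' exclusion disk, restricted to the upper half-plane (rows above the
#' centre bin) so that of the two conjugate lobes the one giving positive
#' phase delay under the package's carrier sign convention is selected
#' deterministically.  Ties are broken toward the larger column index,
#' then the smaller row index.  The default window half-size is half the
#' Chebyshev distance from the peak to the DC bin -- the largest square
#' window guaranteed not to overlap DC -- clipped to the spectrum bounds.
#'
#' @param spec A \code{complex_spectrum}.
#' @param dc_exclusion_radius Radius in bins of the disk around DC to
#'   ignore (default 8, must be >= 1).
#' @param half_size Optional override of the window half-size in bins.
#' @return Object of class \code{sidelobe_window}: list with
#'   \code{center_bin}, \code{half_size} (both \code{c(row, col)}),
#'   \code{peak_magnitude} and \code{snr} (peak over median off-DC
#'   magnitude).
#' @export
locate_sidelobe <- function(spec, dc_exclusion_radius = 8, half_size = NULL) {
  stopifnot(inherits(spec, "complex_spectrum"), dc_exclusion_radius >= 1)
  mag <- Mod(spec$values)
  nr <- nrow(mag); nc <- ncol(mag)
  dcr <- dc_bin(nr); dcc <- dc_bin(nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  off_dc <- (rows - dcr)^2 + (cols - dcc)^2 > dc_exclusion_radius^2
  med <- stats::median(mag[off_dc])
  cand <- off_dc & rows < dcr
  if (!any(cand)) stop_holo("no sidelobe: empty search region",
                            "holoRI_no_sidelobe")
  pk <- max(mag[cand])
  # absolute degeneracy floor: an unmodulated image leaves only FFT
  # round-off outside DC, orders of magnitude below the DC magnitude
  if (pk < 3 * med || pk <= 1e-9 * sum(abs(mag[!off_dc])) || pk == 0)
    stop_holo("no sidelobe: spectral peak indistinguishable from background (unmodulated or blank image)",
              "holoRI_no_sidelobe")
  hits <- which(cand & mag == pk, arr.ind = TRUE)
  hits <- hits[order(-hits[, 2], hits[, 1]), , drop = FALSE]
  cr <- unname(hits[1, 1]); cc <- unname(hits[1, 2])
  cheb <- max(abs(cr - dcr), abs(cc - dcc))
  h <- if (is.null(half_size)) cheb %/% 2 else as.integer(half_size)
  # keep the window inside the spectrum bounds
  h <- min(h, cr - 1, nr - cr, cc - 1, nc - cc)
  if (h < 1) stop("sidelobe too close to the spectrum edge for any window")
  structure(list(center_bin = c(row = cr, col = cc),
                 half_size = c(row = h, col = h),
                 peak_magnitude = pk, snr = pk / med),
            class = "sidelobe_window")
}

#' Demodulate an off-axis hologram
#'
#' Crops the selected sideband window out of the centred spectrum,
#' re-centres it on the DC bin of an otherwise zero spectrum of the
#' original shape, and inverse transforms.  The argument of the complex
#' field is the wrapped object phase (up to a global offset, fixed later
#' by the annular background subtraction); the modulus estimates
#' \code{P_R * P_O}.  With \code{taper = TRUE} a raised-cosine (Hann)
#' taper is applied to the cropped window to soften truncation ringing;
#' the default is the hard rectangular crop.
#'
#' @param holo An \code{\link{interferogram}}.
#' @param window A \code{sidelobe_window}, or \code{NULL} to locate it
#'   automatically.
#' @param taper Apply a raised-cosine window to the cropped sub-spectrum.
#' @param dc_exclusion_radius Passed to \code{\link{locate_sidelobe}}
#'   when \code{window} is \code{NULL}.
#' @param half_size Optional half-size override for automatic location.
#' @return List with \code{phase} (a wrapped \code{\link{phase_map}}),
#'   \code{amplitude} (matrix) and the \code{window} used.
#' @export
demodulate <- function(holo, window = NULL, taper = FALSE,
                       dc_exclusion_radius = 8, half_size = NULL) {
  stopifnot(inherits(holo, "interferogram"))
  spec <- fourier_spectrum(holo)
  if (is.null(window))
    window <- locate_sidelobe(spec, dc_exclusion_radius, half_size)
  S <- spec$values
  nr <- nrow(S); nc <- ncol(S)
  cr <- window$center_bin[["row"]]; cc <- window$center_bin[["col"]]
  hr <- window$half_size[["row"]]; hc <- window$half_size[["col"]]
  if (cr - hr < 1 || cr + hr > nr || cc - hc < 1 || cc + hc > nc)
    stop("sidelobe window leaves the spectrum bounds")
  sub <- S[(cr - hr):(cr + hr), (cc - hc):(cc + hc), drop = FALSE]
  if (taper) {
    wr <- 0.5 - 0.5 * cos(2 * pi * seq_len(2 * hr + 1) / (2 * hr + 2))
    wc <- 0.5 - 0.5 * cos(2 * pi * seq_len(2 * hc + 1) / (2 * hc + 2))
    sub <- sub * outer(wr, wc)
  }
  out <- matrix(0 + 0i, nr, nc)
  dcr <- dc_bin(nr); dcc <- dc_bin(nc)
  out[(dcr - hr):(dcr + hr), (dcc - hc):(dcc + hc)] <- sub
  field <- stats::fft(ifftshift2(out), inverse = TRUE) / (nr * nc)
  list(phase = phase_map(wrap_phase(Arg(field)), wrapped = TRUE),
       amplitude = Mod(field),
       window = window)
}
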