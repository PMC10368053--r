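#' Circular region of interest for the hemispherical thickness model
#'
#' The circle manually fitted around the specimen: its radius
#' parameterizes the spherical chord model, and the annulus of width
#' \code{ring_width} just outside it supplies the background phase
#' level.  Working radii of 45--60 um are typical for mouse embryos, but
#' any positive radius is accepted.
#'
#' @param x,y Centre in micrometres.
#' @param radius Radius R in micrometres.
#' @param ring_width Width of the background annulus in micrometres
#'   (default 5).
#' @return Object of class \code{circular_roi}.
#' @export
circular_roi <- function(x, y, radius, ring_width = 5) {
  stopifnot(radius > 0, ring_width > 0)
  structure(list(x = x, y = y, radius = radius, ring_width = ring_width),
            class = "circular_roi")
}

#' Chord height of the hemispherical specimen model
#'
#' Geometric path length through a sphere of radius R at in-plane
#' distance r from the ROI centre: \code{h = 2 sqrt(R^2 - r^2)} inside
#' the silhouette (the factor 2 covers both hemispheres) and 0 outside.
#'
#' @param roi A \code{\link{circular_roi}}.
#' @param x,y Pixel coordinates in micrometres (vectorized).
#' @return Chord lengths in micrometres.
#' @examples
#' roi <- circular_roi(0, 0, 50)
#' chord_height(roi, 0, 0)            # 2R
#' chord_height(roi, 50 / sqrt(2), 0) # R sqrt(2)
#' @export
chord_height <- function(roi, x, y) {
  r2 <- (x - roi$x)^2 + (y - roi$y)^2
  2 * sqrt(pmax(roi$radius^2 - r2, 0))
}

roi_radius_grid <- function(roi, config) {
  g <- pixel_grids(config)
  sqrt((g$x - roi$x)^2 + (g$y - roi$y)^2)
}

#' Annular background subtraction
#'
#' Subtracts from the whole field the scalar mean phase measured in the
#' annulus \code{[R, R + ring_width]} just outside the ROI, fixing the
#' phase zero level to the specimen-free background.  After subtraction
#' the annulus mean is zero to round-off.
#'
#' @param phase An unwrapped \code{\link{phase_map}}.
#' @param roi A \code{\link{circular_roi}}.
#' @param config An \code{\link{optical_config}}.
#' @return The background-subtracted \code{\link{phase_map}}.
#' @export
background_subtract <- function(phase, roi, config) {
  stopifnot(inherits(phase, "phase_map"), inherits(roi, "circular_roi"),
            inherits(config, "optical_config"))
  if (phase$wrapped) stop("background_subtract expects an unwrapped phase map")
  fw <- config$image_shape[2] * config$pixel_pitch
  fh <- config$image_shape[1] * config$pixel_pitch
  rout <- roi$radius + roi$ring_width
  if (roi$x - rout < 0 || roi$x + rout > fw ||
      roi$y - rout < 0 || roi$y + rout > fh)
    stop("background annulus leaves the image")
  r <- roi_radius_grid(roi, config)
  ring <- r >= roi$radius & r <= rout
  if (sum(ring) < 50)
    stop("background annulus covers fewer than 50 pixels")
  phase_map(phase$values - mean(phase$values[ring]), wrapped = FALSE)
}

#' Per-pixel effective refractive index from unwrapped phase
#'
#' Inverts the hemispherical projection model: at each pixel inside the
#' ROI the effective index is
#' \deqn{n_s = \Delta\phi / (k h) + n_m}
#' with \code{k = 2 pi / lambda} and \code{h} the chord height of the ROI
#' sphere at that pixel.  Pixels whose chord falls below
#' \code{h_min_frac * 2R} (the thin rim, where the vanishing denominator
#' amplifies noise) are masked invalid, as are pixels outside the
#' plausibility band \code{[n_m - 0.05, n_m + 0.1]} -- flagged, never
#' clipped, to preserve evidence of reconstruction failure.
#'
#' @param phase An unwrapped, background-subtracted
#'   \code{\link{phase_map}}.
#' @param roi A \code{\link{circular_roi}}.
#' @param config An \code{\link{optical_config}}.
#' @param h_min_frac Minimum chord as a fraction of the diameter
#'   (default 0.1).
#' @param bounds Plausibility band offsets below/above \code{n_medium}
#'   (default \code{c(-0.05, 0.1)}).
#' @return Object of class \code{ri_map}: list with the \code{values}
#'   matrix (NA outside the ROI), logical \code{mask} of valid pixels,
#'   \code{n_medium}, the \code{roi}, and \code{summary} (mean, median,
#'   n_valid over valid pixels).
#' @export
compute_ri <- function(phase, roi, config, h_min_frac = 0.1,
                       bounds = c(-0.05, 0.1)) {
  stopifnot(inherits(phase, "phase_map"), inherits(roi, "circular_roi"),
            inherits(config, "optical_config"))
  if (phase$wrapped) stop("compute_ri expects an unwrapped phase map")
  stopifnot(h_min_frac >= 0, h_min_frac < 1)
  g <- pixel_grids(config)
  h <- chord_height(roi, g$x, g$y)
  r <- roi_radius_grid(roi, config)
  k <- wavenumber(config)
  inside <- r < roi$radius & h >= h_min_frac * 2 * roi$radius
  values <- matrix(NA_real_, nrow(h), ncol(h))
  values[inside] <- phase$values[inside] / (k * h[inside]) + config$n_medium
  lo <- config$n_medium + bounds[1]
  hi <- config$n_medium + bounds[2]
  mask <- inside & !is.na(values) & is.finite(values) &
    values >= lo & values <= hi
  if (!any(mask)) stop("no valid pixels in the refractive-index map")
  v <- values[mask]
  structure(
    list(values = values, mask = mask, n_medium = config$n_medium,
         roi = roi, h_min_frac = h_min_frac, bounds = bounds,
         summary = list(mean = mean(v), median = stats::median(v),
                        n_valid = sum(mask))),
    class = "ri_map")
}

#' @export
print.ri_map <- function(x, ...) {
  cat(sprintf("<ri_map> %d valid px, mean %.5f, median %.5f (n_medium %.4f)\n",
              x$summary$n_valid, x$summary$mean, x$summary$median, x$n_medium))
  invisible(x)
}

#' Histogram and mode detection for a refractive-index map
#'
#' Normalized frequency distribution of the valid-pixel index values,
#' with simple peak detection: local maxima of the bin counts separated
#' by at least two bins, subject to a relative-prominence rule (the
#' valley between a candidate and any higher accepted peak must drop
#' below \code{prominence} times the candidate height) that suppresses
#' shoulder wiggles.  Zona-shell phantoms produce the characteristic
#' double peak: a left mode at the zona index and a right mode at the
#' cytoplasm index.
#'
#' @param rimap An \code{\link{ri_map}}.
#' @param bins Number of histogram bins (default 40, must be >= 2).
#' @param prominence Relative prominence threshold in (0, 1]
#'   (default 0.5).
#' @param min_height Minimum mode height as a fraction of the tallest
#'   bin (default 0.05), suppressing stray outlier bins.
#' @return List with \code{breaks}, \code{mids}, \code{density}
#'   (frequencies summing to 1), \code{counts} and \code{modes} (data
#'   frame with \code{bin}, \code{ri}, \code{height}, ordered by
#'   increasing index).
#' @export
ri_histogram <- function(rimap, bins = 40, prominence = 0.5,
                         min_height = 0.05) {
  stopifnot(inherits(rimap, "ri_map"), bins >= 2)
  v <- rimap$values[rimap$mask]
  if (!length(v)) stop("empty valid mask")
  breaks <- seq(min(v), max(v), length.out = bins + 1)
  if (breaks[1] == breaks[bins + 1])
    breaks <- breaks[1] + seq(-1e-9, 1e-9, length.out = bins + 1)
  hs <- graphics::hist(v, breaks = breaks, plot = FALSE)
  f <- hs$counts
  B <- length(f)
  left <- c(-Inf, f[-B]); right <- c(f[-1], -Inf)
  cand <- which(f >= min_height * max(f) & f > 0 & f >= left & f >= right)
  cand <- cand[order(-f[cand], cand)]
  modes <- integer(0)
  for (i in cand) {
    ok <- TRUE
    for (m in modes) {
      if (abs(i - m) < 3) { ok <- FALSE; break }
      valley <- min(f[min(i, m):max(i, m)])
      if (valley >= prominence * f[i]) { ok <- FALSE; break }
    }
    if (ok) modes <- c(modes, i)
  }
  modes <- sort(modes)
  list(breaks = hs$breaks, mids = hs$mids,
       density = f / sum(f), counts = f,
       modes = data.frame(bin = modes, ri = hs$mids[modes],
                          height = f[modes]))
}
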