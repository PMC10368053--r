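#' Phase map container
#'
#' A 2D phase field in radians plus a flag saying whether it is still
#' wrapped into \code{(-pi, pi]} or has been unwrapped to a continuous
#' optical-path-difference field.
#'
#' @param values Numeric matrix of phase values (radians).
#' @param wrapped Logical; \code{TRUE} for a wrapped field.
#' @return Object of class \code{phase_map}.
#' @export
phase_map <- function(values, wrapped) {
  stopifnot(is.matrix(values), is.numeric(values), is.logical(wrapped))
  if (wrapped && length(values) &&
      (min(values) <= -pi - 1e-9 || max(values) > pi + 1e-9))
    stop("wrapped phase must lie in (-pi, pi]")
  structure(list(values = values, wrapped = wrapped), class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d, %s, range [%.3f, %.3f] rad\n",
              nrow(x$values), ncol(x$values),
              if (x$wrapped) "wrapped" else "unwrapped",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Specification of a synthetic embryo-like phase phantom
#'
#' Describes a transparent multi-compartment specimen as a collection of
#' spheres of refractive-index excess \code{delta_n} over the medium, an
#' optional spherical shell standing in for the zona pellucida, and an
#' optional cavity sphere (blastocoel) whose negative \code{delta_n}
#' offsets the enclosing cytoplasm.  All contributions to the optical
#' path are additive, so overlapping components simply accumulate
#' effective index.  A smooth polynomial background phase and the beam
#' amplitudes and noise settings used by \code{\link{synthesize_hologram}}
#' complete the description.
#'
#' @param spheres Data frame with columns \code{x, y, radius, delta_n}
#'   (micrometres and dimensionless index excess); may have zero rows.
#' @param shell Optional list \code{(x, y, inner_radius, outer_radius,
#'   delta_n)} for the zona shell.
#' @param cavity Optional list \code{(x, y, radius, delta_n)} with
#'   \code{delta_n <= 0} modelling a fluid-filled cavity.
#' @param background_poly Optional coefficient matrix \code{P}; the
#'   background phase added at \code{(x, y)} is
#'   \code{sum_ij P[i+1, j+1] (x/L)^i (y/L)^j} radians, with \code{L} the
#'   larger field dimension in micrometres.
#' @param amplitude_reference,amplitude_object Real beam amplitudes
#'   \code{P_R} and \code{P_O}.
#' @param noise List \code{(photon_scale, seed)}; \code{photon_scale} is
#'   the expected photon count per unit intensity for Poisson shot noise,
#'   or \code{NULL} for a noiseless hologram.
#' @param stage,lipid Optional descriptive labels.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(spheres = empty_spheres(),
                         shell = NULL,
                         cavity = NULL,
                         background_poly = NULL,
                         amplitude_reference = 1,
                         amplitude_object = 0.8,
                         noise = list(photon_scale = NULL, seed = NULL),
                         stage = NA_character_,
                         lipid = NA_character_) {
  spheres <- as.data.frame(spheres)
  stopifnot(all(c("x", "y", "radius", "delta_n") %in% names(spheres)))
  if (nrow(spheres) && any(spheres$radius <= 0))
    stop("all sphere radii must be positive")
  if (!is.null(shell)) {
    stopifnot(shell$inner_radius >= 0, shell$outer_radius > 0)
    if (shell$inner_radius > shell$outer_radius)
      stop("shell inner_radius must not exceed outer_radius")
  }
  if (!is.null(cavity)) {
    stopifnot(cavity$radius > 0)
    if (cavity$delta_n > 0)
      stop("cavity delta_n must be negative or zero")
  }
  structure(
    list(spheres = spheres, shell = shell, cavity = cavity,
         background_poly = background_poly,
         amplitude_reference = amplitude_reference,
         amplitude_object = amplitude_object,
         noise = noise, stage = stage, lipid = lipid),
    class = "phantom_spec")
}

empty_spheres <- function() {
  data.frame(x = numeric(0), y = numeric(0),
             radius = numeric(0), delta_n = numeric(0))
}

# chord length through a sphere at in-plane distance r from its centre
sphere_chord <- function(x, y, cx, cy, radius) {
  d2 <- (x - cx)^2 + (y - cy)^2
  2 * sqrt(pmax(radius^2 - d2, 0))
}

check_in_field <- function(cx, cy, radius, config, what) {
  fw <- config$image_shape[2] * config$pixel_pitch
  fh <- config$image_shape[1] * config$pixel_pitch
  if (cx - radius < 0 || cx + radius > fw ||
      cy - radius < 0 || cy + radius > fh)
    stop(sprintf("%s (centre %.1f, %.1f, radius %.1f um) leaves the %.1f x %.1f um field of view",
                 what, cx, cy, radius, fw, fh))
}

#' Ground-truth phase of a phantom
#'
#' Renders the unwrapped phase accumulated by a plane wave traversing the
#' phantom under the projection approximation: at each pixel the phase
#' difference is the wavenumber times the sum over components of
#' index excess times geometric chord length.  A sphere of radius R
#' contributes \code{2 sqrt(R^2 - r^2)} inside its silhouette and zero
#' outside; a shell contributes the outer-sphere chord minus the
#' inner-sphere chord; the background polynomial is added as-is.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param config An \code{\link{optical_config}}.
#' @return An unwrapped \code{\link{phase_map}}.
#' @examples
#' cfg <- optical_config()
#' sp <- phantom_spec(spheres = data.frame(x = 76.8, y = 76.8,
#'                                         radius = 50, delta_n = 0.004))
#' ph <- phantom_phase(sp, cfg)
#' max(ph$values)  # ~ 2 k R delta_n
#' @export
phantom_phase <- function(spec, config) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(config, "optical_config"))
  g <- pixel_grids(config)
  k <- wavenumber(config)
  phi <- matrix(0, config$image_shape[1], config$image_shape[2])
  if (nrow(spec$spheres)) {
    for (i in seq_len(nrow(spec$spheres))) {
      s <- spec$spheres[i, ]
      check_in_field(s$x, s$y, s$radius, config, "sphere")
      phi <- phi + k * s$delta_n * sphere_chord(g$x, g$y, s$x, s$y, s$radius)
    }
  }
  if (!is.null(spec$shell)) {
    sh <- spec$shell
    check_in_field(sh$x, sh$y, sh$outer_radius, config, "shell")
    phi <- phi + k * sh$delta_n *
      (sphere_chord(g$x, g$y, sh$x, sh$y, sh$outer_radius) -
         sphere_chord(g$x, g$y, sh$x, sh$y, sh$inner_radius))
  }
  if (!is.null(spec$cavity)) {
    cv <- spec$cavity
    check_in_field(cv$x, cv$y, cv$radius, config, "cavity")
    phi <- phi + k * cv$delta_n * sphere_chord(g$x, g$y, cv$x, cv$y, cv$radius)
  }
  if (!is.null(spec$background_poly)) {
    P <- as.matrix(spec$background_poly)
    L <- max(config$image_shape) * config$pixel_pitch
    u <- g$x / L; v <- g$y / L
    for (i in seq_len(nrow(P)))
      for (j in seq_len(ncol(P)))
        if (P[i, j] != 0) phi <- phi + P[i, j] * u^(i - 1) * v^(j - 1)
  }
  phase_map(phi, wrapped = FALSE)
}

#' Synthesize an off-axis interferogram from a phase field
#'
#' Forms the camera-plane intensity of the interference between a plane
#' reference beam of amplitude \code{P_R} and a tilted object beam of
#' amplitude \code{P_O} carrying the specimen phase:
#' \deqn{I = P_R^2 + P_O^2 + 2 P_R P_O \cos(\Delta\phi + \alpha x + \beta y)}
#' with x, y in micrometres.  Optional Poisson shot noise is applied at
#' \code{photon_scale} expected photons per intensity unit, and the
#' result is scaled to the camera's full range (the noiseless maximum
#' \code{(P_R + P_O)^2} maps to \code{2^bit_depth - 1}), rounded to
#' integer grey levels and clipped.
#'
#' @param truth An unwrapped \code{\link{phase_map}}.
#' @param spec A \code{\link{phantom_spec}} (amplitudes and noise are
#'   taken from here).
#' @param config An \code{\link{optical_config}}.
#' @return Object of class \code{interferogram}: list with the integer
#'   \code{pixels} matrix and the \code{config}.
#' @export
synthesize_hologram <- function(truth, spec, config) {
  stopifnot(inherits(truth, "phase_map"), inherits(config, "optical_config"))
  if (truth$wrapped) stop("truth phase must be unwrapped")
  pr <- spec$amplitude_reference
  po <- spec$amplitude_object
  if (pr <= 0) stop("reference amplitude P_R must be positive")
  if (po < 0) stop("object amplitude P_O must be nonnegative")
  if (sqrt(config$tilt_alpha^2 + config$tilt_beta^2) * config$pixel_pitch >= pi)
    stop("carrier tilt violates the Nyquist bound")
  g <- pixel_grids(config)
  I <- pr^2 + po^2 + 2 * pr * po *
    cos(truth$values + config$tilt_alpha * g$x + config$tilt_beta * g$y)
  ps <- spec$noise$photon_scale
  if (!is.null(ps) && is.finite(ps) && ps > 0) {
    I <- with_seed(spec$noise$seed,
                   matrix(stats::rpois(length(I), lambda = as.vector(I) * ps),
                          nrow(I), ncol(I)) / ps)
  }
  maxlvl <- 2^config$bit_depth - 1
  pixels <- round(I / (pr + po)^2 * maxlvl)
  pixels[pixels < 0] <- 0
  pixels[pixels > maxlvl] <- maxlvl
  interferogram(pixels, config)
}

#' Interferogram container
#'
#' @param pixels Nonnegative numeric matrix of camera grey levels.
#' @param config The \code{\link{optical_config}} the image belongs to.
#' @return Object of class \code{interferogram}.
#' @export
interferogram <- function(pixels, config) {
  stopifnot(is.matrix(pixels), all(pixels >= 0))
  structure(list(pixels = pixels, config = config), class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d px, grey levels [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}
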