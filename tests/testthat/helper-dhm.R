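# Shared fixtures (built in code, nothing on disk) and independent oracles.

# package defaults: 512 px @ 0.3 um/px, carrier at 1/8 diagonal Nyquist
cfg_default <- function() optical_config()

# "adequate carrier separation" configuration used by the round-trip
# fidelity properties: sidelobe at 2/3 of the diagonal Nyquist limit
cfg_wide <- function() optical_config(carrier_frac = 2 / 3)

# small, fast geometry with the same 153.6 um field of view
cfg_small <- function(carrier_frac = 1 / 8)
  optical_config(pixel_pitch = 0.6, image_shape = c(256L, 256L),
                 carrier_frac = carrier_frac)

field_centre <- function(config)
  c(x = config$image_shape[2] * config$pixel_pitch / 2,
    y = config$image_shape[1] * config$pixel_pitch / 2)

sphere_spec <- function(config, radius = 50, delta_n = 0.004, ...) {
  ctr <- field_centre(config)
  phantom_spec(spheres = data.frame(x = ctr[["x"]], y = ctr[["y"]],
                                    radius = radius, delta_n = delta_n), ...)
}

# forward + inverse pipeline on a phantom spec; roi defaults to the
# sphere/embryo outline
run_roundtrip <- function(spec, config, roi = NULL, ...) {
  if (is.null(roi)) {
    roi <- attr(spec, "roi")
    if (is.null(roi)) {
      ctr <- field_centre(config)
      roi <- circular_roi(ctr[["x"]], ctr[["y"]], max(spec$spheres$radius))
    }
  }
  truth <- phantom_phase(spec, config)
  holo <- synthesize_hologram(truth, spec, config)
  rec <- reconstruct_hologram(holo, roi, ...)
  list(truth = truth, holo = holo, rec = rec, roi = roi)
}

rms <- function(x) sqrt(mean(x^2))

# offset-free residual between an unwrapped recovery and the truth
offset_free <- function(recovered, truth) {
  d <- recovered - truth
  d - mean(d)
}

# Oracle: chord length through a sphere by brute-force line integration
# of the interior indicator on a fine z grid.
chord_by_integration <- function(radius, r, dz = 1e-4) {
  z <- seq(-radius, radius, by = dz * radius)
  sum((z^2 <= radius^2 - r^2)) * dz * radius
}

# Oracle: exact two-sided Mann-Whitney p by enumeration of all
# assignments of the pooled ranks to group a (no ties assumed).
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# smooth random field: low-order 2D cosine mixture, max gradient < pi/px
smooth_random_field <- function(nr, nc, amp = 6, seed = 1) {
  set.seed(seed)
  ii <- matrix(seq_len(nr), nr, nc) / nr
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc
  f <- matrix(0, nr, nc)
  for (m in 1:3) {
    f <- f + stats::runif(1, -1, 1) *
      cos(2 * pi * (stats::runif(1, 0.3, 1.5) * ii +
                    stats::runif(1, 0.3, 1.5) * jj) + stats::runif(1, 0, 2 * pi))
  }
  amp * f / max(abs(f))
}
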