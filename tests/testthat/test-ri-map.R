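test_that("chord_height implements the hemisphere geometry", {
  roi <- circular_roi(10, 20, 50)
  expect_equal(chord_height(roi, 10, 20), 100)             # centre: 2R
  expect_equal(chord_height(roi, 60, 20), 0)               # rim
  expect_equal(chord_height(roi, 10 + 50 / sqrt(2), 20),
               50 * sqrt(2), tolerance = 1e-12)            # r = R/sqrt(2)
  expect_equal(chord_height(roi, 200, 200), 0)             # outside
})

test_that("background_subtract zeroes the annulus and removes offsets", {
  cfg <- cfg_small()
  ctr <- field_centre(cfg)
  roi <- circular_roi(ctr[["x"]], ctr[["y"]], 50)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]

  const <- phase_map(matrix(3.7, nr, nc), wrapped = FALSE)
  out <- background_subtract(const, roi, cfg)
  expect_true(all(abs(out$values) < 1e-12))

  # adding a constant offset leaves the index map untouched
  spec <- sphere_spec(cfg, 50, 0.004)
  truth <- phantom_phase(spec, cfg)
  ri0 <- compute_ri(background_subtract(truth, roi, cfg), roi, cfg)
  shifted <- phase_map(truth$values + 3.7, wrapped = FALSE)
  ri1 <- compute_ri(background_subtract(shifted, roi, cfg), roi, cfg)
  expect_equal(ri0$values, ri1$values, tolerance = 1e-10)

  # a 0.2 rad linear ramp across the ROI moves the interior mean < 0.2%
  g <- holoRI:::pixel_grids(cfg)
  ramp <- 0.2 * (g$x - ctr[["x"]]) / (2 * roi$radius)
  ri2 <- compute_ri(background_subtract(
    phase_map(truth$values + ramp, wrapped = FALSE), roi, cfg), roi, cfg)
  expect_lt(abs(ri2$summary$mean - ri0$summary$mean) / ri0$summary$mean,
            0.002)

  # annulus must fit the image and hold enough pixels
  expect_error(background_subtract(const, circular_roi(5, 5, 20), cfg),
               "annulus")
  tiny <- optical_config(pixel_pitch = 10, image_shape = c(8L, 8L))
  expect_error(
    background_subtract(phase_map(matrix(0, 8, 8), wrapped = FALSE),
                        circular_roi(40, 40, 20, ring_width = 1), tiny),
    "50 pixels")
})

test_that("compute_ri inverts the forward chord model", {
  cfg <- cfg_small()
  ctr <- field_centre(cfg)
  roi <- circular_roi(ctr[["x"]], ctr[["y"]], 50)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]

  # zero phase: the medium everywhere
  flat <- phase_map(matrix(0, nr, nc), wrapped = FALSE)
  ri <- compute_ri(flat, roi, cfg)
  expect_true(all(abs(ri$values[ri$mask] - 1.336) < 1e-14))

  # exact inversion: same R, no noise, no demodulation -> n_m + delta_n at
  # every valid pixel to machine precision
  spec <- sphere_spec(cfg, 50, 0.004)
  truth <- phantom_phase(spec, cfg)
  ri2 <- compute_ri(background_subtract(truth, roi, cfg), roi, cfg)
  expect_lt(max(abs(ri2$values[ri2$mask] - (1.336 + 0.004))), 1e-10)
  # centre pixel: delta phi = 2 k R delta_n exactly inverts
  ctr_px <- which.min((holoRI:::pixel_grids(cfg)$x - ctr[["x"]])^2 +
                      (holoRI:::pixel_grids(cfg)$y - ctr[["y"]])^2)
  expect_equal(ri2$values[ctr_px], 1.336 + 0.004, tolerance = 1e-12)

  # monotonicity of the mean in delta_n
  means <- vapply(c(0.002, 0.004, 0.006), function(dn) {
    tr <- phantom_phase(sphere_spec(cfg, 50, dn), cfg)
    compute_ri(background_subtract(tr, roi, cfg), roi, cfg)$summary$mean
  }, 1)
  expect_true(all(diff(means) > 0))

  # mask safety: no NaN/Inf among valid pixels even with h -> 0 included
  ri3 <- compute_ri(background_subtract(truth, roi, cfg), roi, cfg,
                    h_min_frac = 0)
  expect_true(all(is.finite(ri3$values[ri3$mask])))

  # implausible phase masks out; fully implausible errors
  wild <- phase_map(matrix(500, nr, nc), wrapped = FALSE)
  expect_error(compute_ri(wild, roi, cfg), "no valid pixels")
})

test_that("ri_histogram separates zona and cytoplasm modes", {
  cfg <- cfg_small()
  ctr <- field_centre(cfg)
  shell <- list(x = ctr[["x"]], y = ctr[["y"]], inner_radius = 40,
                outer_radius = 45, delta_n = 0.002)
  roi <- circular_roi(ctr[["x"]], ctr[["y"]], 45)

  # uniform sphere reconstructed through the pipeline: unimodal
  rt <- run_roundtrip(sphere_spec(cfg_wide(), 45, 0.004), cfg_wide(),
                      roi = circular_roi(76.8, 76.8, 45))
  expect_equal(nrow(ri_histogram(rt$rec$rimap)$modes), 1)

  # sphere + zona shell: exactly two modes, cytoplasm on the right
  mk <- function(dn_cyto) {
    sp <- phantom_spec(spheres = data.frame(x = ctr[["x"]], y = ctr[["y"]],
                                            radius = 40, delta_n = dn_cyto),
                       shell = shell)
    tr <- phantom_phase(sp, cfg)
    compute_ri(background_subtract(tr, roi, cfg), roi, cfg)
  }
  h_low <- ri_histogram(mk(0.004))
  expect_equal(nrow(h_low$modes), 2)
  expect_gt(h_low$modes$ri[2], h_low$modes$ri[1])
  # left (zona) mode sits near n_m + delta_n_zona
  expect_lt(abs(h_low$modes$ri[1] - 1.338), 5e-4)

  # high-lipid series: right mode moves right, zona mode stays
  h_high <- ri_histogram(mk(0.006))
  expect_equal(nrow(h_high$modes), 2)
  expect_gt(h_high$modes$ri[2], h_low$modes$ri[2])
  expect_lt(abs(h_high$modes$ri[1] - h_low$modes$ri[1]), 5e-4)

  expect_error(ri_histogram(mk(0.004), bins = 1))
})
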