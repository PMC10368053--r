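test_that("phantom_phase matches the chord model and its oracles", {
  cfg <- cfg_small()

  empty <- phantom_phase(phantom_spec(), cfg)
  expect_false(empty$wrapped)
  expect_true(all(empty$values == 0))

  # single sphere: centre value is 2 k R delta_n; off-centre values match
  # a brute-force line integral through the sphere
  R <- 50; dn <- 0.004
  spec <- sphere_spec(cfg, R, dn)
  ph <- phantom_phase(spec, cfg)
  k <- 2 * pi / cfg$wavelength
  ctr <- field_centre(cfg)
  g <- holoRI:::pixel_grids(cfg)
  nearest <- which.min((g$x - ctr[["x"]])^2 + (g$y - ctr[["y"]])^2)
  r0 <- sqrt((g$x[nearest] - ctr[["x"]])^2 + (g$y[nearest] - ctr[["y"]])^2)
  expect_equal(ph$values[nearest], k * dn * 2 * sqrt(R^2 - r0^2),
               tolerance = 1e-12)
  expect_lt(abs(max(ph$values) - 2 * k * R * dn), 2e-4)
  for (r_probe in c(0, 17.3, 42)) {
    px <- which.min(abs(g$x - (ctr[["x"]] + r_probe)) + abs(g$y - ctr[["y"]]))
    r_px <- sqrt((g$x[px] - ctr[["x"]])^2 + (g$y[px] - ctr[["y"]])^2)
    expect_equal(ph$values[px], k * dn * chord_by_integration(R, r_px),
                 tolerance = 1e-3)
  }

  # degenerate shell contributes nothing
  ctrl <- phantom_spec(shell = list(x = ctr[["x"]], y = ctr[["y"]],
                                    inner_radius = 40, outer_radius = 40,
                                    delta_n = 0.002))
  expect_true(all(phantom_phase(ctrl, cfg)$values == 0))

  # additivity of components
  a <- sphere_spec(cfg, 30, 0.002)
  b <- phantom_spec(shell = list(x = ctr[["x"]], y = ctr[["y"]],
                                 inner_radius = 40, outer_radius = 45,
                                 delta_n = 0.002))
  ab <- phantom_spec(spheres = a$spheres, shell = b$shell)
  expect_equal(phantom_phase(ab, cfg)$values,
               phantom_phase(a, cfg)$values + phantom_phase(b, cfg)$values,
               tolerance = 1e-12)

  # geometry must fit the field of view
  off <- phantom_spec(spheres = data.frame(x = 5, y = 5, radius = 50,
                                           delta_n = 0.004))
  expect_error(phantom_phase(off, cfg), "field of view")
})

test_that("synthesize_hologram obeys the interference closed forms", {
  cfg <- cfg_small()
  pr <- 1; po <- 0.8
  flat <- phase_map(matrix(0, cfg$image_shape[1], cfg$image_shape[2]),
                    wrapped = FALSE)
  spec <- phantom_spec(amplitude_reference = pr, amplitude_object = po)
  holo <- synthesize_hologram(flat, spec, cfg)

  maxlvl <- 2^cfg$bit_depth - 1
  scale <- maxlvl / (pr + po)^2
  expect_true(all(holo$pixels >= 0 & holo$pixels <= maxlvl))
  # mean intensity P_R^2 + P_O^2 (integer-bin carrier averages the cosine
  # out exactly); quantization allows half-level slack
  expect_equal(mean(holo$pixels) / scale, pr^2 + po^2, tolerance = 1e-3)
  # fringe contrast 2 P_R P_O / (P_R^2 + P_O^2)
  imax <- max(holo$pixels) / scale; imin <- min(holo$pixels) / scale
  expect_equal((imax - imin) / (imax + imin), 2 * pr * po / (pr^2 + po^2),
               tolerance = 1e-3)
  # fringe period 2 pi / |carrier|: count cycles along a row via the FFT bin
  expect_error(synthesize_hologram(flat,
    phantom_spec(amplitude_reference = 0), cfg), "P_R")
  expect_error(synthesize_hologram(flat,
    phantom_spec(amplitude_object = -1), cfg), "P_O")

  # Nyquist-violating carrier is rejected at synthesis
  bad <- cfg
  bad$tilt_alpha <- 0.99 * pi / cfg$pixel_pitch
  bad$tilt_beta <- 0.99 * pi / cfg$pixel_pitch
  expect_error(synthesize_hologram(flat, spec, bad), "Nyquist")
})

test_that("noiseless spectrum has exactly a DC lobe and two conjugate sidelobes", {
  cfg <- cfg_small()
  rt <- run_roundtrip(sphere_spec(cfg, 40, 0.003), cfg)
  mag <- Mod(fourier_spectrum(rt$holo)$values)
  nr <- nrow(mag); nc <- ncol(mag)
  dcr <- nr %/% 2 + 1; dcc <- nc %/% 2 + 1
  # peaks: local maxima above 5% of the global off-DC max
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  thr <- 0.05 * max(mag[abs(rows - dcr) + abs(cols - dcc) > 4])
  peaks <- which(mag > thr, arr.ind = TRUE)
  # cluster hits by nearest expected lobe centre
  bins <- round(cfg$tilt_alpha * nc * cfg$pixel_pitch / (2 * pi))
  expected <- rbind(c(dcr, dcc),
                    c(dcr - bins, dcc + bins),
                    c(dcr + bins, dcc - bins))
  d2 <- sapply(seq_len(3), function(i)
    (peaks[, 1] - expected[i, 1])^2 + (peaks[, 2] - expected[i, 2])^2)
  nearest <- apply(cbind(d2), 1, which.min)
  expect_setequal(unique(nearest), 1:3)           # all three lobes present
  # every remaining peak sits within the object bandwidth of a lobe
  expect_true(all(apply(cbind(d2), 1, min) < 25))
})

test_that("shot noise is seeded, bit-reproducible and bounded", {
  cfg <- cfg_small()
  spec <- sphere_spec(cfg, 40, 0.004,
                      noise = list(photon_scale = 1e4, seed = 42L))
  truth <- phantom_phase(spec, cfg)
  h1 <- synthesize_hologram(truth, spec, cfg)
  h2 <- synthesize_hologram(truth, spec, cfg)
  expect_identical(h1$pixels, h2$pixels)
  expect_true(all(h1$pixels >= 0 & h1$pixels <= 2^cfg$bit_depth - 1))
  spec2 <- sphere_spec(cfg, 40, 0.004,
                       noise = list(photon_scale = 1e4, seed = 43L))
  h3 <- synthesize_hologram(truth, spec2, cfg)
  expect_false(identical(h1$pixels, h3$pixels))
})

test_that("make_embryo_series is deterministic and lipid scales only delta_n", {
  for (st in c("2cell", "4cell", "8cell", "morula", "blastocyst")) {
    s1 <- make_embryo_series(st, "low", seed = 7L)
    s2 <- make_embryo_series(st, "low", seed = 7L)
    expect_identical(s1, s2)
    hi <- make_embryo_series(st, "high", seed = 7L)
    expect_equal(hi$spheres[c("x", "y", "radius")],
                 s1$spheres[c("x", "y", "radius")])
    expect_equal(hi$spheres$delta_n, s1$spheres$delta_n * 1.5)
    expect_equal(hi$shell$delta_n, s1$shell$delta_n)
    # geometry stays inside the zona cavity (cleavage) / shell (blastocyst)
    d <- sqrt((s1$spheres$x - s1$shell$x)^2 + (s1$spheres$y - s1$shell$y)^2)
    expect_true(all(d + s1$spheres$radius <= s1$shell$outer_radius + 1e-9))
  }
  expect_error(make_embryo_series("16cell", "low", 1L), "unknown stage")
})
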