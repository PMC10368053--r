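# holoRI

Off-axis digital holographic microscopy (DHM) without a microscope:
**holoRI** simulates off-axis interferograms of embryo-like spherical
phase phantoms, recovers the object phase by Fourier sideband
demodulation and reliability-sorted unwrapping, and converts phase into
per-pixel effective refractive-index (RI) maps through a hemispherical
thickness model.  It is aimed at quantitative-phase-imaging researchers
who want a fully testable, laboratory-free reimplementation of the
single-shot DHM analysis chain used to quantify the refractive index of
preimplantation embryos (a proxy for intracellular lipid content),
together with the accompanying group statistics and sensitivity
analyses.

## The model

Light of wavenumber `k = 2π/λ` crossing a transparent specimen of index
`n_s` embedded in medium `n_m` over thickness `h` accumulates the phase
difference

```
Δφ = k (n_s − n_m) h .
```

Modelling the specimen as a sphere of radius `R` centred on a circular
ROI, the chord at in-plane distance `r` from the centre is
`h = 2 √(R² − r²)`, so the per-pixel effective index is recovered as

```
n_s(i) = Δφ_i / (2 k √(R² − r_i²)) + n_m .
```

The phase itself is encoded on a spatial carrier by tilting the
reference beam by `(α, β)`:

```
I = P_R² + P_O² + 2 P_R P_O cos(Δφ + αx + βy) ,
```

whose Fourier transform carries the object spectrum in two conjugate
sidelobes.  Cropping one sidelobe, re-centring it and inverse
transforming yields the wrapped phase; the Herraez reliability-sorting
algorithm unwraps it; the mean phase in an annulus just outside the ROI
fixes the zero level.

## Worked example

```r
library(holoRI)

cfg <- optical_config()                   # 512 px @ 0.3 um/px, 532 nm,
                                          # n_m = 1.336, carrier 1/8 Nyquist
rp  <- representative_phantom(cfg)        # sphere: R = 50 um, delta_n = 0.004
truth <- phantom_phase(rp$spec, cfg)
holo  <- synthesize_hologram(truth, rp$spec, cfg)
rec   <- reconstruct_hologram(holo, rp$roi)
rec$rimap
#> <ri_map> 86428 valid px, mean 1.33976, median 1.33985 (n_medium 1.3360)
```

The reconstructed mean RI is `n_m + Δn = 1.340` to within 2.4e-4 — the
residual comes from the finite sideband crop at the deliberately narrow
default carrier.  The sensitivity analyses reproduce the robustness
bounds of the method:

```r
radius_sensitivity(unwrap_phase(demodulate(holo)$phase), rp$roi, cfg)
#>   fraction radius  mean_ri    rel_change rel_change_pct
#> 1    -0.15   42.5 1.338674 -0.0008115423    -0.08115423
#> 2     0.00   50.0 1.339762  0.0000000000     0.00000000
#> 3     0.15   57.5 1.338175 -0.0011842101    -0.11842101
```

A ±15 % error in the analysis radius moves the mean RI by at most
0.12 % (bound: 0.5 %); a 0.2 rad tilt+curvature background moves it by
0.003 % (bound: 0.2 %); and the dosimetry helper
`energy_density(30e-6, 60, 780e-6)` returns `0.377 ≈ 0.4 J/cm²`.

Seeded embryo phantoms for the five preimplantation stages come from
`make_embryo_series("2cell" | "4cell" | "8cell" | "morula" |
"blastocyst", lipid_level = "low" | "high", seed)`; `run_pipeline()`
reconstructs whole cohorts and runs the normality-gated t/Mann-Whitney
comparisons and the ANOVA + Tukey stage analysis.

## Command line

```sh
inst/cli/dhm simulate    --stage morula --lipid high --seed 3 --out-dir runs/
inst/cli/dhm reconstruct runs/morula_high_seed3_holo.tif \
                         --roi 76.8,76.8,45 --out-dir runs/
inst/cli/dhm analyze     runs/summaries.csv --out-dir runs/
inst/cli/dhm sensitivity --out-dir runs/
```

## Layout

- `R/` — phantom generator, hologram synthesis, demodulation, RI
  mapping, statistics, TIFF/JSON I/O, pipeline and CLI.
- `src/herraez.cpp` — reliability-sorting phase unwrapper.
- `vignettes/dhm-phase-to-ri.Rmd` — methods notes: model, assumptions,
  parameter choices, numerical conventions, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
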