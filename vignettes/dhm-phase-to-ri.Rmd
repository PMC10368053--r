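---
title: "From off-axis holograms to refractive-index maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From off-axis holograms to refractive-index maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoRI)
```

## The measurement model

Off-axis digital holographic microscopy encodes the optical-path
difference of a transparent specimen in a single camera frame.  holoRI
implements the whole chain under the *projection approximation*: a ray
through a specimen of index $n_s$ in medium $n_m$ over thickness $h$
accumulates

$$\Delta\phi = k\,(n_s - n_m)\,h, \qquad k = 2\pi/\lambda .$$

A tilted reference beam of amplitude $P_R$ interferes with the object
beam $P_O e^{i\Delta\phi}$ to give the interferogram

$$I = P_R^2 + P_O^2 + 2 P_R P_O \cos(\Delta\phi + \alpha x + \beta y),$$

whose spectrum consists of a DC lobe plus two conjugate sidelobes at
$\pm(\alpha,\beta)/2\pi$.  Demodulation crops one sidelobe, re-centres
it and inverse transforms; the argument of the resulting complex field
is the wrapped phase.  After unwrapping, the hemispherical chord model
inverts the phase to a per-pixel *effective* index,

$$n_s^{(i)} = \frac{\Delta\phi_i}{2k\sqrt{R^2 - r_i^2}} + n_m ,$$

where $R$ is the radius of a circular ROI fitted around the specimen
and $r_i$ the in-plane distance of pixel $i$ from its centre.  The
index is "effective" in the sense of a thickness-weighted average along
each chord; multi-compartment specimens therefore produce smoothly
varying maps, not segmentations.

### Assumptions

* **Pure phase object**: absorption is neglected; $P_O$ and $P_R$ are
  spatially uniform.
* **Projection approximation**: no diffraction or defocus inside the
  specimen; the phase is a straight-line integral.  This is the same
  approximation the chord model itself requires.
* **Near-spherical specimen**: the thickness model is exact only for a
  sphere concentric with the ROI.  Mis-centred or aspherical specimens
  bias the rim, which is why the mean is taken over a chord-guarded
  mask (below).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `wavelength` | 0.532 | µm | green single-frequency laser typical of live-cell DHM |
| `pixel_pitch` | 0.3 | µm/px | 512 px span ≈ 154 µm, the scale of an embryo field of view |
| `n_medium` | 1.336 | — | physiological culture medium |
| `carrier_frac` | 1/8 | of diagonal Nyquist | well-separated sidelobes at modest fringe density |
| `dc_exclusion_radius` | 8 | bins | keeps the DC lobe out of the sidelobe search |
| window `half_size` | auto | bins | half the Chebyshev DC–sidelobe distance: the largest square window that cannot overlap DC |
| `h_min_frac` | 0.1 | of 2R | rim guard: excludes chords shorter than 10 % of the diameter where the $1/h$ factor amplifies noise |
| `ring_width` | 5 | µm | background annulus just outside the ROI |
| plausibility `bounds` | (−0.05, +0.1) | around $n_m$ | flags (never clips) implausible pixels |
| `alpha` | 0.05 | — | significance level of all group tests |

The carrier is snapped to an exact integer number of DFT bins per axis
(23 at the default geometry).  Two reasons: a leakage-free carrier in
simulation, and — more importantly — integer-bin demodulation leaves no
residual linear phase, which the downstream scalar ring subtraction
could not remove.  The carrier's y-component is negative so that the
sidelobe selected by the deterministic upper-half-plane rule yields
*positive* phase for $n_s > n_m$.

## The synthetic world

`make_embryo_series()` renders seeded phantoms for five preimplantation
stages.  What it emulates:

* additive multi-compartment geometry — cytoplasm spheres (index excess
  0.004, or 0.006 in the "high-lipid" group), a zona-pellucida shell
  (0.002, outer radius 45 µm), and for the blastocyst an expanded
  52 µm embryo whose fluid cavity is cancelled back to the medium
  index;
* conserved cytoplasm volume across cleavage divisions (2 × 19 µm
  blastomeres through 16 × 9.55 µm at the morula), so cleavage-stage
  mean RI is roughly flat while the cavity-dominated blastocyst drops —
  the qualitative stage profile the statistics module must detect;
* carrier fringes, smooth polynomial background phase, Poisson shot
  noise at a configurable photons-per-intensity-unit scale, and
  quantization to the camera bit depth.

What it does *not* emulate: diffraction and partial coherence, specimen
absorption, aberrations beyond a polynomial background, camera read
noise, or biological variability of the index values themselves (the
index excesses are plausible round numbers, not measured values).  A
green test therefore establishes the correctness of the *inverse
chain*, not the biological accuracy of any particular RI number.

## Numerical choices

* **Demodulation window**: hard rectangular crop by default, matching
  the classical procedure; a raised-cosine taper is available
  (`taper = TRUE`) for ringing-sensitive work.  Integer-bin centring
  only — no sub-bin carrier estimation.
* **Round-trip fidelity**: the hemisphere rim has unbounded spatial
  bandwidth, so crop truncation dominates the phase error.  At the 1/8
  Nyquist default the uniform-sphere round trip is ~0.07 rad RMS;
  with the carrier at 2/3 of the diagonal Nyquist limit ("adequate
  separation", `carrier_frac = 2/3`) all stage phantoms round-trip at
  0.011–0.014 rad RMS.  The fidelity properties are tested in that
  regime; mean-RI quantities are insensitive to the difference and are
  tested at the default.
* **Unwrapping**: reliability scores are inverse root-sum-square
  wrapped second differences (horizontal, vertical, both diagonals);
  edges of the 4-connected graph are merged in descending summed
  reliability with a stable sort, ties broken by row-major edge index;
  the smaller union-find group is re-levelled by the integer multiple
  of $2\pi$ bringing the merged edge within $\pi$.  Border pixels get
  the lowest score and merge last; vanishing second differences map to
  a large finite ceiling (1e12).  Output is bit-deterministic and
  congruent to the input modulo $2\pi$ at every pixel.  The global
  $2\pi$ level is deliberately *not* fixed here but by the ring
  subtraction, the single place that defines the phase zero.
* **Background sensitivity convention**: the probe distortion is
  $A\,(u/2 + (u^2+v^2-1)/4)$ in ROI-normalized coordinates, whose range
  over the ROI disk is exactly the quoted peak-to-peak amplitude $A$
  (0.2 rad by default).  The robustness bound is verified under this
  declared convention only.
* **Degenerate inputs**: zero-variance groups fall back to
  Mann-Whitney with a warning flag; sub-3 samples skip the
  Shapiro-Wilk gate (treated as non-normal); blank interferograms
  raise a typed "no sidelobe" error using both a 3× median-magnitude
  rule and an absolute floor relative to the DC magnitude, because a
  numerically blank spectrum contains only FFT round-off.

## Open design points, resolved

* *Analysis radius vs ring subtraction*: perturbing the analysis radius
  (sensitivity target) re-runs the **whole** analysis — annulus and
  chord model — at the perturbed radius, since that is what an analyst
  mis-drawing the ROI would do.
* *Chord for shell pixels*: the chord model is applied uniformly across
  the ROI (which includes the zona), rather than per-compartment; the
  ROI is defined to encompass the zona.
* *Two-sided tests throughout*; the "unpaired t-test" is Student's
  equal-variance version.  Both test branches are always reachable via
  `force =` for audit.
* *Statistic reported for Mann-Whitney*: the U statistic of the first
  group.
* *Histogram modes*: local maxima at least two bins apart, subject to a
  0.5 relative-prominence rule and a 5 % minimum-height rule — the
  minimal machinery that returns exactly two modes for a zona + cell
  phantom without hand-tuning per image.

## Limitations

* The effective-index map is not a tomogram; axial structure is
  averaged along each chord.
* Values within ~`h_min_frac` of the rim are excluded by design; the
  reported "mean RI" is the mean over the guarded valid mask.
* User-supplied holograms with a carrier far from a DFT bin will show a
  residual linear phase after integer-bin demodulation; it largely
  cancels in disk means (cf. the tilt term of the background
  sensitivity) but is visible in phase maps.
* No auto-segmentation: ROIs are supplied by the analyst, as in the
  manual workflow the package mirrors.
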