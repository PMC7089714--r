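---
title: "Focal-line back-projection for linear-array PACT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal-line back-projection for linear-array PACT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pactrecon)
```

## The imaging problem

A linear ultrasound array (here: 128 elements, 2.25 MHz centre frequency,
8.6 cm aperture) is scanned mechanically along the elevation axis over a few
centimetres, recording photoacoustic pressure traces after every laser
pulse. Stacking all element traces over all scan positions gives a 3D
sinogram `p(time, element, scan position)`; reconstruction inverts it to the
initial pressure distribution `p0(r)`, which maps optical absorption
(vasculature, in the motivating application).

The package works in a right-handed frame (depth *z*, lateral *x*,
elevation *y*), millimetres and microseconds throughout, with the array at
*z* = 0 looking into +*z*. A volume such as 200 × 430 × 200 voxels therefore
reads depth × probe-width × scan-distance.

## Universal back-projection and its integrand

Each voxel accumulates, over every element *e* and scan position *s*,

p0(v) = Σ_{e,s} w(v, e, s) · b_{e,s}( τ(v, e, s) ),

where `b = 2 p − 2 t ∂p/∂t` is the back-projection integrand, τ the
time-of-flight model, and *w* a weighting. Design choices:

* **Derivative scheme.** The continuous formula is discretized with
  second-order central differences, first-order one-sided at the two ends of
  each trace. A smooth trace converges at second order as the sampling rate
  doubles (tested); a pure ramp `p = c·t` is annihilated exactly at interior
  samples, the discrete echo of the analytic identity `2ct − 2t·c = 0`.
* **Absolute time.** The *t* multiplying the derivative is the physical
  time of flight `t0 + k/fs`, not the sample index, and `t0` may be
  negative (pre-trigger samples; see the focal-line model below).
* **Plain delay-and-sum** (`integrand = "das"`) is provided alongside, since
  published linear-array pipelines vary in whether they carry the derivative
  term; the full integrand is the default.
* **Fractional delays** are evaluated by linear interpolation between the
  two bracketing samples; times outside the recorded window contribute 0.
* An optional zero-phase Butterworth **band-pass** models the element
  bandwidth but is off by default: the baseline pipeline back-projects the
  raw integrand.

## Time-of-flight: point vs focal line

The point model, `τ = |r_d − v| / v_s`, is exact for point-like detectors
but biased for cylindrically focused arrays, whose acoustic lens focuses
each element on the common focal line at depth *F* (the elevation focal
length). The package's focal-line model treats each element's focus as a
**virtual point detector**:

τ(v) = ( F ± |v − f_e| ) / v_s,

with `f_e = (F, x_e, y_e)` the element's focus, + for voxels beyond the
focal plane and − in front of it. The focus-to-voxel distance is the full
3D distance, so the lateral offset between voxel and element column is
inside the ± term. This is the standard virtual-detector construction for
elevation-focused linear arrays, and it is the single largest modelling
interpretation in the package; alternatives exist that weight contributions
by the proximity of the propagation path to the focal line, and none is
applied here (the physics statement that the crossing path dominates is not
itself a weighting prescription).

Consequences worth knowing:

* On the element axis the model is continuous and strictly monotone in
  depth, and it reduces to the straight-line path `z / v_s` exactly.
  *Off* axis the ± branch switch at the focal plane is a genuine
  discontinuity of the virtual-detector idealization; it is inherent to the
  construction, not a numerical artifact.
* `F = 0` is special-cased to the point model exactly (the unfocused limit),
  and `max |τ_focal − τ_point| → 0` as `F → 0` (tested at F = 1, 0.1, 0.01,
  0 mm).
* In front of the focus the path difference `F − |v − f_e|` can be
  **negative**: a source near the array can arrive "before" the laser
  trigger in virtual-detector time. Simulation fixtures that exercise the
  focal-line model therefore include pre-trigger samples (`t0 < 0`); real
  acquisitions handle the same thing through their trigger delay.
* The elevation focal length of the reference acquisition's customized probe
  is not published; fixtures use 15 mm, a typical value for a 2.25 MHz
  elevation-focused probe, and the parameter is fully configurable
  (`focal_length_mm` in the config; 0 = unfocused default).

## Weighting and normalization

The continuous formula normalizes by the detection solid angle Ω₀, but the
published discrete weighting convention varies. Two are offered:

* `uniform` (default): every contributing (element, position) pair counts
  equally and the sum is divided by the number of contributors — Ω₀ absorbed
  into a count. Chosen as default for reproducibility; with it, absolute
  image scale is declared *not* reproducible against any particular
  published image (those are displayed on arbitrary scale anyway).
* `solid_angle`: each term weighted by cosθ / d², θ the angle between the
  voxel-to-element ray and the element normal, renormalized per voxel.

An optional acceptance-angle mask (half-angle in degrees off the element
normal) can exclude far-off-axis pairs; no cut is applied by default.

## Numerical choices

* **Grid.** RF is the reciprocal of the voxel size; per-axis voxel counts
  are `round(extent × rf)` with half-away-from-zero rounding (base R's
  banker's rounding would make 86 mm × RF 5 irreproducible across
  platforms). Voxel centres sit at `corner + (i − 1/2)/rf`, indices 1-based,
  so index ↔ coordinate round-trips exactly (tested exhaustively on small
  grids). The depth extent of the reference volume is not stated anywhere;
  40 mm is inferred from the 200-voxel depth at RF 5 and recorded as
  inferred.
* **Precision.** Delays and accumulation are double precision throughout —
  at full scale a voxel sums 51 200 terms, inviting cancellation. The
  on-disk sinogram format defaults to float32 (matching typical DAQ output)
  with a lossless float64 option.
* **Tiling.** The vectorized core processes depth slabs sized from a memory
  budget (default 1 GB of scratch per element-position pair); tiling is
  asserted in tests to change nothing, bit for bit.
* **Ties and signs.** The depth-encoded MIP projects |p0| (back-projection
  output is signed and the display convention for the envelope is a
  choice, recorded here); argmax ties along depth break toward the
  shallowest voxel.
* **Sampling rate.** The acquisition rate of the reference system is not
  published; the simulator defaults to 4× the centre frequency (9 MHz at
  2.25 MHz), configurable.

## The synthetic-data generator

`simulate_sinogram()` is the package's ground-truth source. It emulates: the
far-field N-shaped bipolar pulse of a uniformly heated sphere (exact closed
form, `p0 (d − v_s t) / 2d` on `|d − v_s t| ≤ a`), ideal point absorbers as
derivative-of-Gaussian pulses whose spectral peak sits at the element centre
frequency, superposition over absorbers, 1/d amplitude falloff, additive
white Gaussian noise with a fixed seed (bit-reproducible), and — crucially —
the *same delay model as the reconstruction*, so forward → inverse
consistency isolates the correctness of the back-projection rather than
model mismatch. Under the focal-line model the N-shape is centred at the
virtual-detector arrival time while its amplitude falls off with the
physical element distance, which keeps the signal well defined for sources
in front of the focus where the naive "effective distance" `τ·v_s` can drop
below the sphere radius.

It deliberately does **not** emulate: transducer directivity and
finite-aperture diffraction, the element impulse response (a band-pass
receiver model exists but is off by default so the forward model remains the
exact counterpart of the reconstruction), acoustic heterogeneity,
attenuation, or speckle-like clutter. Passing the forward–inverse tests
therefore demonstrates geometric and numerical correctness of the
reconstruction chain, not robustness to the physics a real breast
acquisition adds. Vasculature is approximated as chains of overlapping
spheres (`vessel_phantom`, spacing ≤ radius).

## Problem sizes used in testing

The test-suite and acceptance sizes are chosen as the smallest instances
that still exercise every code path meaningfully: oracle equivalence runs
the triple-loop reference against the vectorized core on ≥ 20 randomized
instances of ≤ 16³ voxels, ≤ 8 elements, ≤ 10 positions (both delay models,
both weightings, random t0 and sampling rates); point recovery runs the
reference acquisition scaled to 32 elements × 50 scan lines at RF 2
(40 × 40 × 10 voxels, five point absorbers at distinct off-grid-symmetry
positions, noise-free), where both delay models localize every source to
the exact voxel. Full-scale 128 × 400 reconstructions use the identical
code path via the same tiling machinery.

## Known limitations

* The focal-line model is an idealization; its off-axis branch
  discontinuity and the absence of path-proximity weighting are the places
  a practitioner reconciling against other focal-line implementations
  should look first.
* Homogeneous speed of sound only; no refraction, attenuation or
  heterogeneous maps.
* Absolute reconstructed amplitude depends on the weighting convention and
  is not calibrated to pressure units.
* The pure-R reference loop is an oracle, not a production path; at full
  acquisition scale only the vectorized core is practical, and no GPU
  backend is included.
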