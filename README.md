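# pactrecon

3D image reconstruction for **linear-array photoacoustic computed tomography
(PACT)** in R, aimed at anyone processing elevation-scanned linear-array
photoacoustic data: a vectorized universal back-projection core with a
focal-line (virtual point detector) delay model, an analytic forward
simulator for ground-truth testing, and depth-encoded maximum-intensity
projection rendering.

## The method

In PACT, a nanosecond laser pulse deposits heat in absorbing tissue (blood,
most prominently); thermoelastic expansion launches ultrasound that an array
records. Universal back-projection recovers the initial pressure
*p₀(r)* from the recorded traces *p(r_d, t)*:

```
p0(r) = (1/Ω0) ∫_S dΩ [ 2 p(r_d, t) − 2 t ∂p(r_d, t)/∂t ]  at  t = |r_d − r| / v_s
```

with *v_s* the speed of sound (1.54 mm/µs default) and Ω₀ the solid angle of
the detection surface. Each voxel sums the conditioned integrand of every
element trace at every scan position, evaluated at that voxel's acoustic time
of flight.

The straight-line delay `|r_d − r|/v_s` is wrong for cylindrically focused
linear arrays: the acoustic lens focuses each element on a **focal line**
through the foci of all elements, and the dominant propagation path crosses
it. `pactrecon` therefore also provides the **focal-line delay model**: each
element's focus acts as a virtual point detector, and the travel path is the
focal length plus (beyond the focus) or minus (in front of it) the
focus-to-voxel distance.

For a full elevation scan (128 elements × 400 scan lines in the reference
acquisition: an 8.6 cm probe scanned over 4 cm at 0.1 mm steps) the sum runs
over 51 200 traces per voxel; the voxel lattice is set by a **resolution
factor** RF, the reciprocal of the voxel size in mm, so RF 5 over
40 × 86 × 40 mm gives a 200 × 430 × 200 volume.

Two reconstruction cores share one contract: `reconstruct()` (vectorized,
tiled over depth slabs) and `reconstruct_reference()` (the plainest possible
triple loop, kept as an independent correctness oracle). The analytic
forward simulator emits the exact N-shaped pulse of a uniformly heated
sphere, so forward → inverse consistency is testable without experimental
data.

## Worked example

Simulate five point absorbers under a scaled-down version of the reference
acquisition (32 elements, 2.25 MHz, elevation focus 15 mm, 50 scan lines at
0.1 mm, RF 2 grid) and reconstruct them with the focal-line model:

```r
library(pactrecon)

fx <- fixture_suite("paper_geometry_small")
fx$geometry
#> Linear array: 32 elements, pitch 0.6719 mm (aperture 20.8 mm), 2.25 MHz, elevation focus at 15 mm

sino <- simulate_sinogram(fx$phantom, fx$geometry, fx$trajectory,
                          sampling_rate = fx$sampling_rate, t0 = fx$t0,
                          duration = fx$duration, model = "focal_line",
                          v_s = fx$v_s)
sino
#> Sinogram: 226 time samples x 32 elements x 50 scan positions @ 9 MHz (t0 = -5 us)

vol <- reconstruct(sino, fx$geometry, fx$trajectory, fx$grid,
                   model = "focal_line", v_s = fx$v_s)
vol
#> Reconstructed volume: 40 x 40 x 10 voxels (0.5 mm), range [-0.972, 4.44]

find_peaks(vol, 5)                       # strongest well-separated maxima (mm)
#>       [,1]  [,2] [,3]
#> [1,] 16.75 -3.25 3.75
#> [2,] 11.25  0.25 2.75
#> [3,]  8.25  3.25 2.25
#> [4,] 14.25  4.75 3.25
#> [5,]  5.25 -4.75 1.25

point_recovery_error(vol, fx$phantom$centers)
#> [1] 0
```

The five recovered peaks are the five true absorber centres, in order of
reconstructed amplitude: every source localizes to the exact voxel
(error 0 voxels). `depth_encoded_mip(vol)` renders the volume as a
depth-coloured projection; `write_volume(vol, "vol.nii")` stores it as NIfTI
with the physical voxel size in the header.

A command-line interface wraps the same pipeline:

```sh
inst/cli/pact-recon simulate    --config geom.yaml --phantom phantom.yaml --out sino.raw
inst/cli/pact-recon reconstruct --sinogram sino.raw --config geom.yaml --out vol.nii --mip mip.png
inst/cli/pact-recon selftest
```

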