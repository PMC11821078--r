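---
title: "Simulating interferometric phase imaging of a cell in a nanoliter well"
author: "anlcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interferometric phase imaging of a cell in a nanoliter well}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(anlcsim)
```

## Scope and model

`anlcsim` models a transmission interference microscope looking at a
single sperm cell held inside an addressable nanoliter container
(ANLC), a micro-well of ~1 nL volume. The physical question it answers
is an instrument-design one: *which well geometry least corrupts the
retrieved quantitative phase image of the cell?* Four geometries are
compared — a pyramid tapering to a ~10 µm tip, a cylinder with a
concave spherical-cap bottom, a truncated pyramid with a ~80 µm tip,
and a flat-bottom cylinder — under an identical imaging chain, cell and
illumination.

The optical model is scalar diffraction throughout. Polarization,
high-NA vectorial effects, partial coherence and reflections are all
outside scope; the instrument being modeled encodes specimen
information purely as an optical path delay, and a scalar treatment
captures exactly that, plus the wall-edge diffraction that creates the
halo artifact under study.

### Wave propagation

Free-space propagation uses the angular-spectrum method: multiply the
field's 2D spectrum by `exp(i 2π z sqrt(1/λ'² − f²))`, with evanescent
components suppressed and the Matsushima band limit applied so that
wrap-around aliasing from the periodic FFT cannot masquerade as signal.
Fields are zero-padded by a factor 2 (`pad_factor`) before each
transform; the crop after each step acts as an absorbing boundary.
Propagation *within* a medium of index `n` uses the reduced wavelength
`λ' = λ/n`.

Transmission through the 3D sample volume offers two forward models:

* **projection** — one multiplicative phase screen
  `exp(i 2π OPD(x, y)/λ)` built from the volume's ground-truth OPD
  `∫(n − n_medium) dz`. It is exact for laterally uniform samples and,
  by construction, free of diffraction artifacts, which makes it the
  package's ground-truth generator and a bookkeeping sanity check: run
  in projection mode, every design scores essentially zero error.
* **multislice** (default) — symmetric split-step: a half-step of
  angular-spectrum propagation, then for each slab its integrated phase
  screen at the slab *center*, separated by full steps, ending on a
  half-step. The symmetric form is second-order accurate in the slice
  thickness; the naive screen-then-step ordering biases the effective
  specimen position by half a slice, which is visible (roughly a
  doubling of the round-trip error) for a cell head only 1.5 µm thick
  sampled at 1 µm slices. Multislice propagation uses the envelope
  convention (the background plane-wave carrier is divided out) so
  that a laterally uniform sample reproduces the projection result
  identically.

The imaging arm is an ideal unit-magnification relay focused at the
cell plane: the camera-plane field is the exit-plane field numerically
back-propagated over the exit-to-focus distance in the medium
background. Real condenser/imaging focal lengths and the magnification
are not modeled — magnification only rescales pixel pitch, and no lens
prescriptions exist for the instrument — so the simulation works in
sample-plane coordinates throughout.

### Interferometry and retrieval

The reference arm is an ideal tilted plane wave carrying a modulator
phase: `E_r ∝ exp(i(2π f_c · r − φ_M))`, with carrier frequency
`f_c = sin(θ)/λ` (default tilt θ = 2°, "a few degrees" class). The
modulator *delays* the reference; under that convention the N-step
phase-shifting estimator

```
φ = atan2(−Σ_k I_k sin φ_k, Σ_k I_k cos φ_k),  φ_k = 2πk/N
```

is exact per pixel for noiseless sinusoidal data — machine-precision
exact, which the tests assert at 1e−9 rad. The default stack uses
N = 4 steps (the instrument's step count is not documented; any N ≥ 3
with uniform coverage works and is validated for conditioning).

Single-shot off-axis retrieval is standard Fourier fringe analysis:
Hann-apodize the frame, isolate the order at −f_c with a circular
filter of radius `0.5 |f_c|`, inverse-transform, demodulate by the
exact carrier in the space domain. The apodization matters: the carrier
is not periodic on the frame, and its spectral leakage rings through a
hard filter at the 1e−2 rad level, versus ~6e−4 with the window. An
optional plane fit (amplitude-weighted circular mean of the phase
gradient) removes the residual ramp left by a carrier mis-specified at
the bin level.

Unwrapping is quality-guided flood fill (compiled, priority-queue
driven), with quality defined as the negated local wrapped-gradient
energy; each connected mask component is unwrapped independently and
fixed to the zero-median 2π branch. On the synthetic data this package
produces, the residual after reference subtraction rarely wraps at all;
the unwrapper exists for the general path and is round-trip tested on
wrapped 5-rad bumps.

Reference subtraction mirrors interferometric practice: the specimen
acquisition and a separately simulated *empty-well* acquisition are
each retrieved to wrapped phase, subtracted modulo 2π, and only the
small residual is unwrapped. Unwrapping the raw well phase directly
would be hopeless — an SU-8 wall edge steps by hundreds of radians
between neighboring pixels — and subtracting the *simulated* empty well
(rather than the analytic well OPD) is what preserves the
design-dependent diffraction residual that the comparison measures.

## The phantoms

`build_anlc()` rasterizes a well onto a voxel grid: SU-8 wall material
(n = 1.59) outside the cavity within the well layer, aqueous medium
(n = 1.33) inside, borosilicate substrate (n = 1.52) below, covering
oil (n = 1.40) above. None of these indices are measured quantities of
the modeled device; they are standard literature values and all
overridable. Pyramids have square cross-sections tapering linearly from
`lateral_dim` to `tip_dim`; cylinders are circular; the concave floor
is a spherical cap of curvature radius `bottom_radius_of_curvature`
(default: the lateral dimension, a shallow bowl spanning the full
diameter — the deepest point on the axis). Closed-form cavity volumes
(`cavity_volume()`) anchor the voxelization tests: a 125 µm / 100 µm
flat cylinder holds 1.227 nL, and the voxelized volume converges to the
closed form well inside 2 % at 1 µm voxels.

`build_sperm()` rasterizes a three-part cell: ellipsoidal head
(default 4.5 × 3.2 × 1.5 µm full axes, n = 1.37), cylindrical midpiece
(4 × 1 µm, n = 1.35) and thin tail (45 × 0.8 µm, n = 1.35), lying in
one plane with an in-plane orientation. Voxelization is exact along the
optical axis — each lateral column gets partial-volume weights from the
analytic chord of each component through each slab — so the peak
ground-truth OPD at the head center equals the closed form
`2 c (n_head − n_medium) = 0.06 µm` to float precision, i.e. a peak
phase of 0.75 rad at λ = 0.5 µm: the default phantom never wraps.
Lateral edges are hard (voxel-center membership), which is the main
reason retrieved-vs-truth errors concentrate on the sub-wavelength
tail.

### Placement: the resting position

`place_phantom_in_anlc()` centers the cell's bounding box on the well
axis and, by default, rests it at the *deepest admissible depth*: the
largest depth at which the cavity cross-section still contains the
cell, minus a 1 µm clearance, with the axial center snapped down to the
slice lattice so the thin head rasterizes symmetrically. This is the
physically meaningful configuration — a cell settles to the bottom of
its container — and it is what differentiates the designs: in the
flat and concave cylinders and the truncated pyramid the cell lies
essentially on the floor, while the 10 µm-tip pyramid cannot admit the
~53 µm-long cell near its tip and holds it ~40 µm up, wedged between
sloping walls that sit squarely inside the illumination beam. An
explicit `depth_fraction` overrides the default for controlled
experiments (a mid-depth placement, for instance, moves every design's
walls away from the cell and mutes the differences).

## Metrics and the design comparison

All fidelity metrics ignore piston (a global phase offset carries no
specimen information):

* `rms_phase_error()` — masked RMS of retrieved − truth after best-fit
  piston removal. The comparison mask is the cell footprint (OPD above
  5 % of peak) dilated by the halo annulus width.
* `halo_ratio()` — residual energy in a 10 µm annulus around the
  footprint divided by the energy inside it, with piston taken from a
  neutral ring just outside the annulus so that a residual confined to
  the footprint scores exactly zero. The halo the instrument shows is
  a visual artifact; 10 µm is this package's choice of where "around
  the cell" ends, not a measured value.
* `relative_rms` — footprint RMS error divided by footprint RMS truth;
  this is the round-trip figure ("retrieved phase matches the actual
  values") and reaches 0.97 % for the flat-bottom cylinder at the
  default study conditions.
* `cross_section()` — interpolated 1D profiles through the cell center.

`compare_designs()` runs the identical pipeline per design and ranks by
`rms_error`. At the defaults (512 × 512 × 0.5 µm grid, 112 × 1 µm
slices, 60 µm waist, λ = 0.5 µm, 4-step retrieval, noiseless camera)
the ranking is flat cylinder ≤ truncated pyramid < concave cylinder <
pyramid, with the pyramid's halo ratio two orders of magnitude above
the flat design's. The flat and truncated designs differ only in the
fifth digit: the truncated tip's edge lies at ±40 µm where the 30 µm
(1/e²) beam radius leaves essentially no light, so both behave as
"no significant distortion" designs. The pipeline is fully
deterministic (no noise by default), so these hairline differences are
stable, but they should be read as "indistinguishable", not as a
meaningful advantage.

## The droplet model

In a water-in-oil droplet, water diffuses into unsaturated oil; with
solute trapped inside, concentration rises as volume falls. The
implemented law is

```
dV/dt = −k (1 − s) g(V),   g(V) = V^(2/3)   (area-limited efflux)
C(t) = C₀ V₀ / V(t)   ⇒   dC/dt = −C (dV/dt)/V
```

with `s` the oil's water-saturation fraction and `k` a transfer
coefficient. The conservation structure and the monotonicity claims
(smaller droplets concentrate faster, diverging as V → 0; saturated
oil freezes C) are the substantive content; the specific `g(V)` is a
modeling choice — the surface-limited form is the natural one for a
diffusive flux through the droplet surface, and a constant-flux mode
is available via `efflux = "constant"`. Units are arbitrary-consistent
(nL, s, a.u.); no attempt is made to fit unpublished transfer
coefficients. Integration uses `deSolve::lsodar` with a root function,
so `time_to_concentration()` is a true root of the integrated
trajectory; for `s = 0` the area law has the closed form
`V(t) = (V₀^{1/3} − kt/3)³`, which the integrator matches to ~1e−10
relative and the tests require at 0.1 %.

## Numerical choices, problem sizes, degenerate inputs

* Default study grid: 512 × 512 lateral voxels at 0.5 µm (256 µm field
  of view around a 125 µm well), 112 axial slices at 1 µm. The full
  four-design comparison takes about four minutes on one CPU; the test
  suite exercises the same pipeline end-to-end at 128 × 128 / 1–2 µm,
  where one design runs in seconds. Axial slices of 1 µm matter: at
  2 µm slabs the fine lateral frequencies of the cell are propagated
  too coarsely and the retrieval error roughly triples at 0.5 µm pitch.
* Phase wrap-to-(−π, π] uses the complex argument, with −π mapped to π
  for determinism. Degenerate modulator spacings are rejected by a
  conditioning check (`|Σ e^{iφ_k}|` and `|Σ e^{2iφ_k}|` must vanish).
* Quantization is off by default (ideal detector); enabling the 14-bit
  camera scales exposure so the brightest possible pixel sits at 80 %
  of full scale, adds optional Gaussian read noise, and rounds. A
  well-exposed 14-bit stack moves the retrieved phase by well under
  1e−3 rad.
* Empty masks, empty annuli, non-fitting phantoms, sub-minimum grids,
  wavelengths outside the simulated 0.4–0.8 µm range and unknown
  configuration keys are all rejected with classed errors
  (`anlcsim_dimension_error`, `anlcsim_config_error`).
* Floating-point rasters are written as true IEEE float32 TIFFs by a
  small writer in the package (the `tiff` CRAN package reads but does
  not write float sample formats); interferogram stacks can also be
  written as 16-bit integer TIFF when quantized. Sidecar YAML files
  carry wavelength, pitch and modulator phases at 15-digit precision.

## What the synthetic data does and does not show

The generator reproduces the *geometry-dependent, coherent* part of the
measurement: Gaussian illumination, thick-specimen diffraction,
wall-edge halos, carrier fringes, phase-step evolution, quantization.
It does not emulate surface roughness of fabricated wells, fabrication
tolerances beyond what the configuration expresses, shot noise
(Gaussian read noise only), mechanical drift between phase steps,
reflections/multiple scattering, a swimming cell, or the true
refractive-index fine structure of a real sperm cell (the phantom is a
three-compartment model with literature indices). Passing the
round-trip and ranking tests therefore demonstrates internal
consistency of the imaging model and the *relative* optical merit of
the well geometries under ideal conditions — not a calibrated
prediction of absolute phase accuracy on a physical instrument.

## Known limitations

* The multislice background index is the aqueous medium everywhere;
  propagation inside wall/substrate material is approximated by phase
  screens over a medium-index background, which is the standard
  multislice trade-off and is shared by specimen and empty-well
  acquisitions (so it largely cancels in the subtraction).
* The lateral rasterization of the thin tail is hard-edged at the voxel
  scale; tail-region errors dominate the round-trip residual.
* Off-axis retrieval trades resolution for single-shot operation (the
  carrier filter passes half the carrier frequency); agreement with
  phase shifting is asserted at 1e−2 rad RMS on band-limited phantoms,
  not in general.
* The droplet model is zero-dimensional: no spatial gradient in the
  oil, no freezing-front thermodynamics, no survival dose–response.
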