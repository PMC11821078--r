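# anlcsim

Scalar-wave simulation of an interference microscope imaging a single
sperm cell inside an **addressable nanoliter container (ANLC)** — a
micro-well of roughly nanoliter volume used to hold one cell through a
freeze–thaw cycle — plus the droplet solute-concentration model that
explains why cells die in sub-nanoliter volumes under unsaturated oil.

## The problem

Shrinking a container to ~100 µm makes it easy to *address* a single
cell, but the container's own walls and floor now sit inside the
illumination beam of any quantitative phase (interference) microscope
used to inspect the cell. Wall-induced diffraction corrupts the
retrieved optical path difference (OPD) map — the "halo" artifact — and
the amount of corruption depends on the well geometry. This package
rebuilds that measurement numerically so the four candidate well designs
can be compared on equal footing:

* **pyramid** tapering to a ~10 µm tip,
* **cylinder with a concave (spherical-cap) bottom**,
* **truncated pyramid** with a ~80 µm tip,
* **flat-bottom cylinder**.

The simulation chain is the real measurement chain:

1. a Gaussian illumination beam (1/e² intensity diameter 60 µm at the
   sample plane, wavelength anywhere in 0.4–0.8 µm) built with
   `make_gaussian()`;
2. a voxelized 3D refractive-index phantom — well + cell — from
   `build_anlc()`, `build_sperm()`, `compose_volumes()`;
3. band-limited angular-spectrum propagation through the volume by
   symmetric split-step **multislice** (`transmit_sample()`), which is
   what lets wall diffraction emerge; a diffraction-free **projection**
   mode is kept as ground-truth generator;
4. interference with a tilted, phase-modulated reference plane wave
   (`interfere()`, `acquire_stack()`) — intensity
   `I = |E_s + E_r|²`, fringe period `λ / sin(tilt)`;
5. phase retrieval: the N-step phase-shifting estimator
   `φ = atan2(−Σ I_k sin φ_k, Σ I_k cos φ_k)` (`retrieve_phase_shifting()`)
   or single-shot Fourier demodulation of the off-axis carrier
   (`retrieve_offaxis()`), followed by quality-guided unwrapping
   (`unwrap()`) and empty-well reference subtraction
   (`subtract_reference()`);
6. fidelity metrics per design: masked RMS phase error against the
   phantom ground truth, the halo ratio (annulus energy ÷ footprint
   energy), peak error and cross-sections (`compare_designs()`).

The companion `droplet_model` integrates
`dV/dt = −k (1 − s) V^{2/3}` with solute conservation
`C(t) V(t) = C₀ V₀`, so `dC/dt = −C V̇ / V`: the smaller the droplet,
the faster its solute concentrates — and water-saturated oil (`s = 1`)
stops the process entirely (`simulate_droplet()`,
`time_to_concentration()`).

## Worked example

```r
library(anlcsim)

cmp <- compare_designs(unname(standard_designs()))
print(cmp)
#> Design comparison (best first):
#>               kind   rms_error  halo_ratio peak_error relative_rms
#>      cylinder_flat 0.001921855 0.001050383 0.02082040  0.009694449
#>  truncated_pyramid 0.001922383 0.001050564 0.02082436  0.009702036
#>   cylinder_concave 0.005056305 0.004994256 0.11648171  0.059605307
#>            pyramid 0.036727620 0.332973477 0.41233624  0.408516243
```

Reading this: the flat-bottom cylinder retrieves the cell phase with the
lowest RMS error (0.0019 rad) and recovers the phantom's ground-truth
OPD to 0.97 % relative RMS over the cell footprint; the truncated
pyramid is indistinguishable from it at this illumination (its tip edge
sits outside the beam). The concave bottom's curvature distorts the
retrieval about 2.6× more, and the pyramid — whose sloping walls wedge
right up against the cell — is an order of magnitude worse, with ~300×
the flat design's halo ratio. That ordering is the design conclusion:
use a flat-bottom cylindrical well.

The droplet side:

```r
tr <- simulate_droplet(droplet_state(V = 1.23, C = 1), oil_spec(0, 1e-3),
                       duration = 2000, dt = 1)
time_to_concentration(droplet_state(1.23, 1), oil_spec(0, 1e-3), 2)
#> [1] 663.1131   # seconds until the solute concentration doubles
time_to_concentration(droplet_state(1.23, 1), oil_spec(1, 1e-3), 2)
#> [1] Inf        # water-saturated oil: concentration never rises
```

A command-line wrapper exposes the same pipeline:

```sh
Rscript scripts/anlcsim.R simulate        --config inst/extdata/configs/four_designs.yaml --out out/
Rscript scripts/anlcsim.R retrieve        --stack out/stack.tif --out out/
Rscript scripts/anlcsim.R compare-designs --config inst/extdata/configs/four_designs.yaml --out out/
Rscript scripts/anlcsim.R droplet         --config inst/extdata/configs/four_designs.yaml
Rscript scripts/anlcsim.R fixtures        --out fixtures/ --seed 1
```

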