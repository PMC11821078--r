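seed: 1.0
output_dir: anlcsim_out
optical:
  wavelength: 0.5
  waist_diameter: 60.0
  tilt_angle: 2.0
  tilt_azimuth: 0.0
  n_steps: 4.0
  mode: multislice
  pad_factor: 2.0
  grid:
    nx: 512.0
    ny: 512.0
    nz: 112.0
    dx: 0.5
    dy: 0.5
    dz: 1.0
  camera:
    bit_depth: 14.0
    noise_std: 0.0
    quantize: no
sample:
  designs:
  - kind: pyramid
  - kind: cylinder_concave
  - kind: truncated_pyramid
  - kind: cylinder_flat
  phantom: []
  depth_fraction: resting
retrieval:
  annulus_width: 10.0
  footprint_threshold: 0.05
  retrieval_mode: phase_shifting
droplet:
  V0: 1.23
  C0: 1.0
  saturation_fraction: 0.0
  transfer_coefficient: 0.001
  duration: 3000.0
  dt: 1.0
  efflux: area
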