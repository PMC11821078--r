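seed: 1.0
output_dir: anlcsim_out
optical:
  wavelength: 0.5
  waist_diameter: 25.0
  tilt_angle: 2.0
  tilt_azimuth: 0.0
  n_steps: 4.0
  mode: multislice
  pad_factor: 2.0
  grid:
    nx: 128.0
    ny: 128.0
    nz: 56.0
    dx: 1.0
    dy: 1.0
    dz: 2.0
  camera:
    bit_depth: 14.0
    noise_std: 0.0
    quantize: no
sample:
  designs:
  - kind: pyramid
    lateral_dim: 100.0
  - kind: cylinder_concave
    lateral_dim: 100.0
  - kind: truncated_pyramid
    lateral_dim: 100.0
    tip_dim: 64.0
  - kind: cylinder_flat
    lateral_dim: 100.0
  phantom:
    tail_length: 20.0
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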