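kinetic_config:
  n_molecules: 10000
  rate_matrix:
    FREE:
      FREE: 0.0
      CHROM: 2.1114576
      RNA: 0.3248396
    CHROM:
      FREE: 0.8120991
      CHROM: 0.0
      RNA: 0.3248396
    RNA:
      FREE: 0.8120991
      CHROM: 2.1114576
      RNA: 0.0
  focus_weights:
  - 0.3333333
  - 0.3333333
  - 0.3333333
  immobile_fraction: 0.0
  bleach_efficiency: 1.0
nucleus_geometry:
  nucleus_radius: 1.2
  foci:
    x:
    - 4.0413344e-17
    - -0.5715768
    - 0.5715768
    'y':
    - 0.66
    - -0.33
    - -0.33
    z:
    - 0.0
    - 0.0
    - 0.0
    radius:
    - 0.15
    - 0.15
    - 0.15
imaging_config:
  frame_interval: 0.06
  n_frames: 120
  bleach_duration: 0.02
  bleach_frame: 11
  bleach_radius: 0.15
  pixel_size: 0.08
  psf_axial_sigma: 0.4
  z_drift_sigma: 0.0
  z_drift_tau: 2.0
  acquisition_bleach_rate: 0.0
  noise_model: poisson
  gain: 10.0
  zstack:
    n_planes: 13.0
    spacing: 0.3
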