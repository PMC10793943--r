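# Desk-scale quickstart: 4 x 4 coded probe, short flow-phantom acquisition,
# matched-filter reconstruction, PDI + CDI. Runs in a few minutes on one CPU:
#
#   inst/cli/cusi pipeline --config inst/extdata/config-quickstart.yaml --out out
probe:
  nx: 4
  ny: 4
  pitch: 1.25e-3
  element_width: 1.25e-3
  f_center: 4.0e+6
  fractional_bw: 0.65
  c: 1500
mask:
  seed: 2
  feature_size: 5.0e-4
  height_range: 1.2e-3
  extent: 6.4e-3
  spacing: 5.0e-5
  c_mask: 2337
freq:
  n: 6
  center: 4.0e+6
  band: 0.5
plane:
  extent: 6.4e-3
  spacing: 5.0e-5
  z: 1.2e-2
pulse:
  n_cycles: 3
grid:
  spacing: 5.0e-5
  dims: [28, 28, 20]
  z_offset: 5.0e-4
phantom:
  type: flow
  speed: 2.0e-2
  radius: 3.5e-4
  density: 150
  seed: 9
  static_fraction: 0
acquisition:
  n_frames: 16
  frame_rate: 500
  noise_sigma: 0
  seed: 11
  scheme: hadamard
preprocess:
  cutoff: 0.65
  jitter_k: 5
  block: 100
  drop: 0
  clutter_filter: false
reconstruct:
  method: matched
  iters: 8
  lambda_factor: 0.2
  phase_only: true
  pad_factor: 2
doppler:
  lag: 1
  subset: .na
  pdi: true
  cdi: true
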