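# Color Doppler of a carotid-like vessel: 256-element array, 4-cycle
# transmit / 1-cycle receive at 2.5 MHz, five plane-wave angles, 10 frames
# per angle at a 5 kHz PRF.  Full scale (hours); use --scale and/or fewer
# elements for desk-scale runs.
mode: doppler
seed: 1
fs_hz: 20000000.0
angles_deg: [-6, -3, 0, 3, 6]
array:
  n_elements: 256
  width_m: 0.0003
  height_m: 0.007
  kerf_m: 0.00005
excitation:
  f0_hz: 2500000.0
  n_cycles: 4
  rx_n_cycles: 1
medium:
  c_m_s: 1540
  rho_kg_m3: 1000
phantom:
  type: vessel
  n_moving: 50000
  n_static: 50000
  radius_m: 0.005
  angle_deg: 45
  center_depth_m: 0.04
  half_length_m: 0.025
  profile: laminar
  peak_speed_m_s: 0.5
  static_region:
    x_m: [-0.03, 0.03]
    y_m: [-0.005, 0.005]
    z_m: [0.01, 0.08]
beamforming:
  x_m: [-0.02, 0.02]
  dx_m: 0.0001569
  z_m: [0.01, 0.08]
  dz_m: 0.001
  f_number: 1.5
doppler:
  prf_hz: 5000
  frames_per_angle: 10
  cutoff_db: 4
output_dir: out_vessel_doppler
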