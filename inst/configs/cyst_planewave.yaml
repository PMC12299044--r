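# Plane wave imaging of the cyst/point-target phantom: 128-element linear
# array, single-cycle 3 MHz excitation, five steering angles.  Full scale;
# pass --scale 0.05 (or scale = 0.05 to run_config) for a desk-scale run.
mode: pw
seed: 1
fs_hz: 16000000.0
angles_deg: [-6, -3, 0, 3, 6]
array:
  n_elements: 128
  width_m: 0.0003
  height_m: 0.007
  kerf_m: 0.00005
excitation:
  f0_hz: 3000000.0
  n_cycles: 1
medium:
  c_m_s: 1540
  rho_kg_m3: 1000
phantom:
  type: cyst
  n_scatterers: 100000
  region:
    x_m: [-0.025, 0.025]
    y_m: [-0.005, 0.005]
    z_m: [0.03, 0.09]
beamforming:
  x_m: [-0.0224, 0.0224]
  dx_m: 0.0001764
  z_m: [0.03, 0.09]
  dz_m: 0.001
  f_number: 2
  dynamic_range_db: 60
output_dir: out_cyst_pw
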