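units:
  system: lennard-jones
  note: eps = sigma_P = m = k_B = 1; see unit_system() for SI scales
run:
  'n': 16
  f: 2.0
  pore_radius: 1.25
  mode: immobile
  k: '.inf'
  T_m: 0.0
  T_p: 1.5
  m_C: 1.0
  dt: 0.005
  xi: 1.0
  n_traj: 1000
  therm_steps: 200000
  max_steps: 1.0e+08
  seed: 1
  cells:
  - 49
  - 28
  d: 0.375
  check_stride: 10
  fail_lateral: 8.0
  fail_sustain: 100000.0
  slab_half: 1.5
  reff_stride: 0
  kf: 30.0
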