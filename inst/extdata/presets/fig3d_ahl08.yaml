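schema: colonyflow-run/1
growth:
  sigma0: 1.0
  n_star: 0.5
  K_sigma: 0.15
  n_sigma: 6.0
  v: 1.0
  sigma_n_tilde: 3.5
circuit:
  alpha_T: 8.0
  alpha_L: 6.0
  alpha_A: 2.0
  K_T: 0.1
  h_T: 2.0
  K_P: 0.5
  K_A: 0.3
  h_A: 10.0
  k_on: 3.0
  k_off: 1.0
  d_T: 0.5
  d_L: 0.05
  d_P: 0.3
  d_A: 0.2
  K_phi: 0.06
  n_phi: 6.0
  b: 0.1
  h_b: 2.0
  R_domain: 1.0
  A0: 0.8
init:
  R0: 0.05
  n0: 1.0
  T0: 0.1
  n_markers: 15
solver:
  rtol: 1.0e-08
  atol: 1.0e-08
  t_end: 60.0
  n_floor_frac: 0.0001
  n_quad: 201
spawn:
  gap: 0.02
  delta: 0.001
  enabled: yes
  max_markers: 400
output:
  n_times: 201
  n_dgrid: 161
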