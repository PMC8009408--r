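schema: colonyflow-run/1
growth:
  sigma0: 1.0
  n_star: 0.5
  K_sigma: 0.5
  n_sigma: 4.0
  v: 1.0
  sigma_n_tilde: 0.5
init:
  R0: 0.1
  n0: 1.0
  T0: 0.1
  n_markers: 10
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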