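name: contracting-cell-gel
energy:
  'N': 100.0
  chi: 0.75
cells:
  tau0: 1.0
  lambda: 1.0
  D: 0.01
mechanics:
  eta_s: 0.25
  xi: 0.5
  R: 0.5
ic:
  kind: uniform
  theta_i: 0.6
  n_i: 1.0
solver:
  dX: 0.002
  dT: 5.0e-4
  t_end: 100.0
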