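preset: cancer
reaction:
  a1: 0.050000000000000003
  a2: 0.00050000000000000001
  a3: 0.0001
  b1: 1
  X0: 0.14999999999999999
  X_th: 0.012
mechanics:
  sigma0_prime: 5
  alpha_LJ: 0.5
  lambda_sc: 0.38054029643567144
  c_soft: 0.19186516217000291
  zeta: 1.1037527593818983
  sigma0: 4.5300000000000002
  gamma: 0.25992104989487319
  m0: 2
  epsilon: 1.2674264999999999e-05
  mu_fric: 0.033333333333333333
  rcut_factor: 2.5
  dt: 3.75
  n_sub: 1
cycle:
  T_CC: 72000
  T_M: 3600
  d_sigma: 6.1325122709571643e-05
density:
  delta_rho: 0.25
  rho_grid: 0.001
initial_concentrations:
- 0.10000000000000001
- 0.40000000000000002
- 0
L: 200000
seed: 1
snapshot_every: 160
options:
  sphere_uniform: no
  neighbor: auto
  max_N: -1
  verbose: no
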