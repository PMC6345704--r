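params:
  L: 12
  alpha_A: 6.0
  alpha_R: 1.0
  alpha_V: 0.5
  alpha_N: 10.0
  alpha_C: 1.0
  alpha_E: 0.5
  sigma_A: 1.0
  eps_V: 0.01
  sigma_N: 1.0
  sigma_SA: 0.6
  sigma_SX: 0.75
  sigma_RP: 0.01
  n_scales: 2
  mu: 1.414213562373095
  lambda_C: 3.4
  kappa: 3.0
  sigma_phi: 0.261799387799149
  eps_C: 0.005
  gamma_occ: 0.8
schedule:
  s0: 1.0
  sR: 0.4
  sM: 0.15
  sB0: 1.0
  sBS: 1.0
  sX0: 1.0
  sXS: 3.0
  sR0: 1.0
  sRS: 1.0
descent:
  max_iter: 150
  final_max_iter: 300
  tol: 1.0e-06
  tol_streak: 3
  step0: 0.1
  grad_floor: 1.0e-12
  max_backtrack: 30
repulsion:
  rho: 0.0002
  dT: 0.004
  tau: 4.0
  tau_max: 16.0
  eps_rep: 0.0004
  max_interpretations: 4
contour:
  v: 1.0
  R: 16.0
  sigma_Q: 0.628318530717959
  g_T: 0.25
  max_steps: 2000
  reinit_every: 20
  k_weight: 0.25
seed: 1
version: bomap-config-1
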