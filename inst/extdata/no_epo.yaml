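scenario:
  name: no_epo
  injury_radius: 0.25
  injury_density: 100.0
  C0: 100.0
  U0: 2.0
  horizon: 240.0
  r_max: 5.0
  n_nodes: 200.0
  out_dt: 1.0
parameters:
  D_R: 0.02
  D_M: 0.0011
  D_F: 0.0014
  D_P: 0.03
  delta_R: 0.04
  delta_M: 0.25
  delta_F: 0.35
  delta_P: 0.015
  sigma_R: 0.0005
  sigma_M: 0.05
  sigma_F: 0.025
  sigma_P: 0.0
  delta_U: 0.03
  lambda_R: 1.0
  lambda_M: 1.0
  lambda_F: 1.0
  lambda_P: 1.0
  Lambda: 400.0
  alpha: 0.005
  beta_1: 0.5
  beta_2: 0.005
  gamma: 0.015
  nu: 0.003
  mu_SA: 0.003
  mu_DN: 0.02
  tau_1: 12.0
  tau_2: 24.0
  P_c: 1.0
metadata:
  units:
    D_R: mm^2/h
    D_M: mm^2/h
    D_F: mm^2/h
    D_P: mm^2/h
    delta_R: 1/h
    delta_M: 1/h
    delta_F: 1/h
    delta_P: 1/h
    sigma_R: conc/h per cell/mm^2
    sigma_M: conc/h per cell/mm^2
    sigma_F: conc/h per cell/mm^2
    sigma_P: conc/h per cell/mm^2
    delta_U: 1/h
    lambda_R: conc
    lambda_M: conc
    lambda_F: conc
    lambda_P: conc
    Lambda: conc
    alpha: 1/h
    beta_1: 1/h
    beta_2: 1/h
    gamma: 1/h
    nu: 1/h
    mu_SA: 1/h
    mu_DN: 1/h
    tau_1: h
    tau_2: h
    P_c: conc
  provenance:
    D_R: calibrated
    D_M: calibrated
    D_F: calibrated
    D_P: calibrated
    delta_R: calibrated
    delta_M: calibrated
    delta_F: calibrated
    delta_P: calibrated
    sigma_R: calibrated
    sigma_M: calibrated
    sigma_F: calibrated
    sigma_P: calibrated
    delta_U: calibrated
    lambda_R: calibrated
    lambda_M: calibrated
    lambda_F: calibrated
    lambda_P: calibrated
    Lambda: calibrated
    alpha: calibrated
    beta_1: calibrated
    beta_2: calibrated
    gamma: calibrated
    nu: calibrated
    mu_SA: calibrated
    mu_DN: calibrated
    tau_1: physiology
    tau_2: physiology
    P_c: calibrated
  h_sharpness: 0.0
  notes: time in hours, space in mm, densities in cells/mm^2; all calibrated values
    are implementer choices, not experimentally determined
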