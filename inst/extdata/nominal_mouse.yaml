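parameters:
  Ls_ref_A: 2.0
  Ls_iso_A: 0.04
  v0_A: 7.0
  Lsc0_A: 1.51
  gamma_rest_A: 0.003
  tau_rise_A: 0.004
  tau_decay_A: 0.006
  tau_sys_A: 0.02
  sigma_act_A: 60.0
  sigma_pas_A: 1.2
  Ls_pas_ref_A: 1.8
  beta_pas_A: 8.0
  k1_A: 8.0
  Ls_ref_V: 2.0
  Ls_iso_V: 0.04
  v0_V: 7.0
  Lsc0_V: 1.51
  gamma_rest_V: 0.003
  tau_rise_V: 0.006
  tau_decay_V: 0.008
  tau_sys_V: 0.04
  sigma_act_V: 230.0
  sigma_pas_V: 0.3
  Ls_pas_ref_V: 1.9
  beta_pas_V: 4.0
  k1_V: 2.5
  tau_offset_A: 0.08
  Vw_LA: 6.0
  Vw_LV: 80.0
  Vw_RA: 6.0
  Vw_RV: 30.0
  Vw_S: 40.0
  Am_ref_LA: 33.0
  Am_ref_LV: 80.0
  Am_ref_RA: 30.0
  Am_ref_RV: 85.0
  Am_ref_S: 15.0
  Ra_val: 0.001
  Rm_val: 0.0005
  Rp_val: 0.001
  Rt_val: 0.0005
  R_vc: 0.0008
  R_pv: 0.001
  R_sys: 0.045
  R_pulm: 0.0025
  C_sa: 5.0
  C_sv: 60.0
  C_pa: 8.0
  C_pv: 20.0
config:
  period: 0.11
  V_un:
    SA: 0.0
    SV: 0.0
    PA: 0.0
    PV: 0.0
  init_volumes:
    LA: 15.0
    LV: 45.0
    RA: 15.0
    RV: 45.0
    SA: 55.0
    SV: 85.0
    PA: 12.0
    PV: 25.0
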