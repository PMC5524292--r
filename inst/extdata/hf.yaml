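schema: cvrsim-scenario-1
condition: hf
units:
  pressure: mmHg
  volume: cm^3
  flow: cm^3/s
  resistance: mmHg.s/cm^3
  compliance: cm^3/mmHg
  time: s
  ventilation: l/min
  speed: rpm
  o2_content: ml/dl
params:
  hr0: 81.0
  ks: 0.3
  relax_frac: 0.3
  lv_Es: 0.5
  lv_V0: 50.0
  lv_a: 0.0532
  lv_b: 0.0194
  rv_Es: 0.37
  rv_V0: -20.0
  rv_a: 0.05
  rv_b: 0.045
  la_C: 5.0
  la_Vu: 15.0
  la_kick: 0.08
  ra_C: 6.0
  ra_Vu: 15.0
  ra_kick: 0.15
  kick_center: 0.925
  kick_width: 0.12
  R_mv: 0.0035
  R_av: 0.006
  R_tv: 0.0035
  R_puv: 0.02
  C_aa: 0.35
  Vu_aa: 60.0
  C_da: 0.75
  Vu_da: 150.0
  R_da: 0.025
  L_da: 0.0022
  Ra_ub: 5.2
  Ra_kid: 5.4
  Ra_sp: 4.0
  Ra_ll: 9.4
  Ra_rl: 9.4
  Rv_ub: 0.35
  Rv_kid: 0.4
  Rv_sp: 0.28
  Rv_ll: 0.35
  Rv_rl: 0.35
  C_ub: 10.0
  C_kid: 3.0
  C_sp: 24.0
  C_ll: 7.0
  C_rl: 7.0
  Vu_ub: 380.0
  Vu_kid: 70.0
  Vu_sp: 1500.0
  Vu_ll: 380.0
  Vu_rl: 380.0
  k3_ub: 4.0
  k3_kid: 0.0
  k3_sp: 4.0
  k3_ll: 4.0
  k3_rl: 4.0
  vn_pressure: 18.0
  C_vc: 32.0
  Vu_vc: 350.0
  k3_vc: 4.0
  R_vc: 0.008
  C_pa_base: 3.2
  Vu_pa: 60.0
  R_ap: 0.18
  C_pv: 7.0
  Vu_pv: 120.0
  R_pv: 0.01
  cap_thresh: 15.0
  cap_slope: 0.05
  cap_floor: 0.5
  tau_wedge: 8.0
  ppl_base: -2.5
  k_pl: 3.0
  Pset: 88.0
  kb: 5.0
  resetting_gain: 1.6
  g_hr: 0.6
  hr_max: 112.0
  hr_min: 45.0
  g_es_lv: 0.03
  g_es_rv: 1.1
  g_r: 0.5
  g_vu: 0.15
  tau_p: 2.0
  tau_hr: 3.0
  tau_sym: 8.0
  met_ref_ub: 10.0
  met_ref_kid: 13.5
  met_ref_sp: 11.0
  met_ref_ll: 10.0
  met_ref_rl: 10.0
  met_floor_ub: 0.55
  met_floor_kid: 0.9
  met_floor_sp: 0.6
  met_floor_ll: 0.13
  met_floor_rl: 0.13
  met_width: 2.5
  tau_met: 15.0
  mp_gain: 5.0
  mp_cadence: 0.9
  weight: 75.0
  vo2_rest: 3.45
  hb: 14.5
  p50: 26.6
  hill_n: 2.7
  co2_c0: 21.5
  co2_slope: 0.6625
  fr_ub: 0.27
  fr_kid: 0.17
  fr_sp: 0.33
  fr_ll: 0.115
  fr_rl: 0.115
  fi_ub: 0.06
  fi_kid: 0.0
  fi_sp: 0.03
  fi_ll: 0.455
  fi_rl: 0.455
  valv: 2.5
  vart: 3.0
  vtis: 2.5
  pio2: 150.0
  ve0: 9.2
  vco2_ref: 207.0
  k_ff: 0.02908
  g_co2: 0.15
  paco2_ref: 35.0
  g_o2: 0.25
  pao2_thr: 60.0
  f0: 12.0
  k_f: 0.8
  vd: 0.3
  tau_ve: 15.0
  vad_on: 0.0
  vad_kw: 1.55e-06
  vad_kq1: 0.8
  vad_kq2: 0.003
  vad_Rc: 0.035
  vad_Lc: 0.005
  vad_wmin: 6000.0
  vad_wmax: 12000.0
  in_vo2_a: 3.45
  in_vo2_b: 3.45
  in_t0: 0.0
  in_ramp: 60.0
  in_rq_a: 0.8
  in_rq_b: 0.8
  in_omega: 9500.0
  vol_shift: 40.0
  suction_V: 10.0
protocol:
- name: rest
  vo2: 3.45
  rq: 0.8
  ramp: 0.0
  max_dur: 300.0
- name: exercise
  vo2: 11.5
  rq: 1.186
  ramp: 60.0
  max_dur: 600.0
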