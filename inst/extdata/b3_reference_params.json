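{
  "k1": 0.007,
  "k_1": 0.2,
  "k2": 2.5,
  "k_2": 4.5,
  "k3": 1.2,
  "k_3": 4,
  "HSPG_tot": 11,
  "FGFR_tot": 1,
  "w_FR": 0.02,
  "k_act_Ras": 24,
  "Km_Ras": 1,
  "d_Ras": 8,
  "k_act_Raf": 24,
  "Km_Raf": 1,
  "d_Raf": 8,
  "k_act_MEK": 24,
  "Km_MEK": 1,
  "d_MEK": 8,
  "k_act_ERK": 24,
  "Km_ERK": 1,
  "d_ERK": 8,
  "NFB_tot": 1,
  "k_nfb": 1.5,
  "d_nfb": 0.35,
  "K_inh": 0.12,
  "h_nfb": 6,
  "k_f": 12,
  "Km_f": 1,
  "k_r": 18,
  "Km_r": 1,
  "rho": 8.0,
  "sigma": 0.02
}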