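{
  "kappa": 0.73,
  "pAm_b": 14.36,
  "pAm_j": 38.77,
  "v_b": 0.0053,
  "v_j": 0.0143,
  "E_G": 2349,
  "p_M": 29.22,
  "k_J": 0.002,
  "kappa_R": 0.95,
  "EH_h": 7.562924441e-06,
  "EH_b": 0.00104,
  "EH_j": 0.0203,
  "EH_p": 1.65,
  "T_A": 8000,
  "T_ref": 293.15,
  "delta_ME": 0.629,
  "delta_M": 0.599,
  "d_V": 0.09,
  "w_E": 23.9,
  "mu_E": 550000,
  "meta": {
    "species": "Xylonora atlantica",
    "model": "abj",
    "T_ref_note": "rates referenced to 293.15 K; user-facing temperatures in degrees C",
    "EH_h_note": "hatching threshold calibrated so that hatching at 4 C with a fully provisioned egg occurs at 5.6 d",
    "T_A_note": "Arrhenius temperature not reported for this species; 8000 K, a standard bivalve value, reproduces the reported temperature scaling of lifespan and growth rate"
  }
}
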