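{
  "tvcl": 14.8,
  "tvvc": 82.5,
  "tvq": 0.178,
  "tvvp": 5.72,
  "theta_scr": -0.192,
  "theta_bsa": 0.301,
  "scr_ref": 0.58,
  "bsa_ref": 1.45,
  "bsv_cl": 0.198,
  "bsv_vc": 0.135,
  "corr_cl_vc": 0.94,
  "bov_cl": 0.151,
  "sigma_prop": 0.309
}
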