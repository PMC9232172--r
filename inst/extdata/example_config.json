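{
  "lambda": 0.12,
  "gamma": 0.04,
  "mu": 5,
  "dt": 0.001,
  "tau_abnormal": 5,
  "tau_normal": "inf",
  "scenario": 1,
  "N_theta": 10,
  "tissue_size": 200,
  "t_end_tau": 20,
  "gs_threshold": 50,
  "seed": 42
}
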