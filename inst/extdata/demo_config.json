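{
  "seed": 20220426,
  "synth": {
    "params": {
      "r_f": 0.0982, "r_s": 0.1096, "r_t": 0.002,
      "m_f": 9000.1, "m_s": 29899.2, "m_t": 42999.8,
      "c_f": 0.001, "c_s": 0.0406, "c_t": 0.0271,
      "alpha": 0.044, "beta": 0.037, "eta": 0.03
    },
    "initial": [1150, 6700, 10300],
    "years": 4,
    "noise_sd": 0.02,
    "seasonal_amp": 0
  },
  "fit": {
    "init_guess": {
      "r_f": 0.0982, "r_s": 0.1096, "r_t": 0.002,
      "m_f": 9000.1, "m_s": 29899.2, "m_t": 42999.8,
      "c_f": 0.001, "c_s": 0.0406, "c_t": 0.0271,
      "alpha": 0.044, "beta": 0.037, "eta": 0.03
    },
    "n_starts": 1,
    "maxiter": 30
  },
  "sweep": {
    "parameter": "alpha",
    "values": [0.022, 0.044, 0.066],
    "t_end": 240
  }
}
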