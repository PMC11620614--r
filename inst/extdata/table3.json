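{
  "constants": {
    "A_t": 7.5,
    "nonsynonymous_fraction": 0.69
  },
  "proteins": {
    "beta_lactamase": {
      "name": "beta-lactamase",
      "length": 263,
      "alpha": 0.104,
      "beta": 0.019,
      "alpha_raw": 0.07176,
      "beta_raw": 0.009048,
      "raw_note": "alpha_raw/beta_raw are back-derived (synthetic) from the published nonsynonymous-rescaled coefficients via the 0.69 fraction; the source publication printed only the rescaled values",
      "schedule": [1.0, 0.61, 0.61, 0.55, 0.55, 0.39],
      "schedule_note": "tolerated fraction per added nonsynonymous mutation; final entry repeats",
      "printed": {"p_th": 0.00051, "n_max": "10-17", "si": "93.6-96.2%"}
    },
    "gfp": {
      "name": "GFP",
      "length": 236,
      "alpha": -0.062,
      "beta": 0.058,
      "exclude_n": [1],
      "printed": {"p_th": 0.00056, "n_max": "12", "si": "95.0%"}
    },
    "hisa": {
      "name": "HisA",
      "length": 245,
      "alpha": 0.165,
      "beta": 0.065,
      "printed": {"p_th": 0.00054, "n_max": "10", "si": "95.9%"}
    }
  }
}
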