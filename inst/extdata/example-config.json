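{
  "seed": 1,
  "tau": 40,
  "quantile": 0.5,
  "min_chars": 15,
  "min_char_len": 2,
  "min_frequency": 5,
  "dim": 100,
  "window": 5,
  "epochs": 20,
  "nboot": 200,
  "scenario": {
    "n_regions": 12,
    "years": [2017, 2018, 2019, 2020],
    "n_words": 6,
    "n_docs": 1500,
    "noise_sd": 0.1,
    "effect_sizes": {"IE": -1, "ACP": 1},
    "n_respondents": 200,
    "pen_start": 0.5,
    "pen_growth": 0.05
  }
}
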