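[
  {
    "reference_id": "synthetic-loglinear-v1",
    "structure": "aao",
    "predictor": "ga_weeks",
    "transform": "log",
    "range": [14, 42],
    "mean": [0.26, 0.051],
    "sd": 0.13
  },
  {
    "reference_id": "synthetic-loglinear-v1",
    "structure": "isthmus_3vt",
    "predictor": "ga_weeks",
    "transform": "log",
    "range": [14, 42],
    "mean": [-0.13, 0.046],
    "sd": 0.15
  }
]
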