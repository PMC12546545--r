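{
  "designs": ["within", "cross", "between"],
  "grid": [
    {"n2": 30, "n1": 50}, {"n2": 60, "n1": 50}, {"n2": 90, "n1": 50},
    {"n2": 30, "n1": 20}, {"n2": 60, "n1": 20}, {"n2": 90, "n1": 20}
  ],
  "R": 500,
  "seed": 1,
  "estimators": ["fs", "croon"],
  "out_dir": "study_fullnested"
}
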