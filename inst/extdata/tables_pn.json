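{
  "designs": ["pn"],
  "grid": [
    {"n2": 30, "n1": 20}, {"n2": 40, "n1": 20}, {"n2": 50, "n1": 10},
    {"n2": 50, "n1": 20}, {"n2": 50, "n1": 30}, {"n2": 80, "n1": 20},
    {"n2": 80, "n1": 30}, {"n2": 100, "n1": 10}, {"n2": 100, "n1": 50}
  ],
  "R": 500,
  "seed": 1,
  "estimators": ["fs", "croon"],
  "out_dir": "study_pn"
}
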