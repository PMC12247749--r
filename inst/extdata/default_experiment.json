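{
  "protocol": {},
  "subject": {"species": "mouse", "tumor": false},
  "generator": {},
  "controllers": [
    {"kind": "CL", "target_db": 36}
  ],
  "predictor": {
    "feature_set": 12,
    "train_runs": 40,
    "epochs": 200,
    "pressure_range": [0.12, 0.40],
    "tumor_fraction": 0.3
  },
  "output_dir": ".",
  "seed": 1
}
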