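{
  "synthetic": {
    "m": 40,
    "n_frames": 400,
    "occupancies": {"A": 0.45, "B": 0.45},
    "transition_fraction": 0.10,
    "noise_sigma": 0.5
  },
  "cutoff": 10,
  "embedding": {"method": "graphsage", "dimension": 16},
  "labeling": {"source": "generative"},
  "split": {"train_fraction": 0.70, "stratified": true},
  "classifier": {"model": "logistic_regression"},
  "out_dir": "mdembed_demo_run",
  "seed": 42
}
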