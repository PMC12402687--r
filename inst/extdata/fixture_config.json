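{
  "out_dir": "axonmetrics-fixture",
  "seed": 42,
  "sigma": 0.1,
  "contact_radius": 0.635,
  "pam": { "n_samples": 4 },
  "stats": { "top_k": 100 },
  "cohort": { "n_patients": 3 }
}
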