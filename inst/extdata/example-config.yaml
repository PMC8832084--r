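# Example pipeline configuration (YAML and JSON share this schema).
master_seed: 2026
cohort:
  n_mt: 37
  n_nmt: 33
  roi_effect: 0.52
models: [intercept, reward, effort2, full]
sampler:
  n_chains: 2
  n_adapt: 400
  n_warmup: 400
  n_iter: 600
rois:
  - {name: acc,            "x": 0,   "y": 14, "z": 46, radius: 6}
  - {name: striatum_right, "x": 22,  "y": 14, "z": 6,  radius: 6}
  - {name: striatum_left,  "x": -14, "y": 6,  "z": 10, radius: 6}
glm:
  tr: 2
  dt: 0.1
  noise_sd: 0.5
stats:
  alpha: 0.05
  q: 0.05
  covariates: [age, sex, pubertal_status]
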