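# One-source orientation assay, D. japonica defaults
assay: oa1l
bf_deg: 40
tau: 0.5
gain: 3
gain_units: radians
wigwag:
  enabled: true
  angle_sd_deg: 18.7
  log_mean: -0.15
  log_sd: 0.44
perturbation:
  left_gain: 1
  right_gain: 1
  left_unshielded: false
  right_unshielded: false
arena:
  radius: 40
  max_events: 400
n_agents: 60
seed: 1
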