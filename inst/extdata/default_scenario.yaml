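# Default simulated-study scenario: a cohort of 40 foragers in groups of 4,
# two four-minute conditions differing only in search cost, latent traits
# uncoupled from strategy unless couplings are set.
cohort:
  n_participants: 40
  coupling: {"O": 0.0, "C": 0.0, "E": 0.0, "A": 0.0, "N": 0.0}
  antisociality_coupling: 0.0
questionnaire_noise_sd: 0.7
randomize_order: true
conditions:
  - name: F5-0s
    search_cost: 0.01
  - name: F5-8s
    search_cost: 8
analysis:
  bootstrap_B: 1000
  ci_level: 0.95
  cutoff_threshold: 12
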