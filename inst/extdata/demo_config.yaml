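# Demonstration pipeline configuration: one stimulus set at reduced scale
# with a small genetic-algorithm budget.  See ?run_pipeline for the schema.
seed: 1
stimuli:
  sets: [mollis]
  n_songs: 10
  L: 33
cohort:
  n_females: 12
  n_cycles: 18
  control_response_prob: 0.02
  exclusion_threshold: 2
fit:
  population: 12
  generations: 6
  polish: true
  polish_maxit: 40
dynamics:
  n_reps: 10000
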