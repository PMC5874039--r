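# Bundled two-species synthetic scenario: simulate a drifted paleoclimate,
# sample occurrences for two virtual species, plant a fossil for the first
# species outside its present-day range, and run the full workflow.
seed: 1
scenario:
  nSpecies: 2
settings:
  evaluation:
    n_reps: 10
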