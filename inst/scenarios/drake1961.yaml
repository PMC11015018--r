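name: drake1961
description: >
  Classic Drake equation with the 1961 educated guesses and the
  optimistic f_i = 1, evaluated by interval arithmetic; optional Monte
  Carlo propagation over the term ranges.
seed: 1961
stages: [drake]
drake:
  mode: interval
  scenario: drake1961
  monte_carlo:
    n_samples: 10000
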