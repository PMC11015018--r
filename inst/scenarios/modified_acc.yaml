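name: modified_acc
description: >
  Modified Drake equation with f_i replaced by f_oc (0.00016-0.011) and
  the f_pt upper bound (0.17), interval-evaluated over the 1961 ranges.
seed: 1961
stages: [drake]
drake:
  mode: interval
  scenario: modified_acc
  monte_carlo:
    n_samples: 10000
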