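name: speciation
description: >
  Sequential speciation chain over a plate-tectonic era: expected chain
  length and replicate quantiles for a constant-rate birth-death lineage
  at the upper end of typical rates.
seed: 77
stages: [speciation]
speciation:
  lambda: 0.5
  mu: 0.1
  horizon: 1000
  n_reps: 5000
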