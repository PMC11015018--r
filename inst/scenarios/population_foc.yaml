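name: population_foc
description: >
  End-to-end stochastic route to f_oc: generate a synthetic exoplanet
  population from the default water-delivery mixture and count the
  fraction inside the radius-dependent permitted window, alongside the
  analytic in-window probability.
seed: 20240412
stages: [population, foc]
population:
  n: 200000
  radius_low: 0.5
  radius_high: 2.35
  water_max: 56
foc:
  method: population
  freeboard_mode: conservative
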