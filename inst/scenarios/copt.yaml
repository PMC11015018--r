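name: copt
description: >
  Remote-sensing COPT form: expected number of planets with long-lived
  coexisting continents, oceans and plate tectonics, using the
  coexistence time L_COPT = 5e8 yr and dropping f_c.
seed: 1961
stages: [copt]
copt:
  mode: copt
  scenario: copt
  monte_carlo:
    n_samples: 10000
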