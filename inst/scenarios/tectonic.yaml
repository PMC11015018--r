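name: tectonic
description: >
  Single-lid to plate-tectonics transition timescales: global plate
  mosaic assembly from trench-lengthening rates, and the transition
  durations bracketed by C-isotope excursions and Snowball glaciations.
stages: [tectonic]
tectonic:
  target_length_km: 55000
  rate_low: 100
  rate_high: 600
  brackets:
    - {label: c_isotope, first: 811, last: 570}
    - {label: glaciation, first: 720, last: 580}
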