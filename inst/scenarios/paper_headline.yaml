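name: paper_headline
description: >
  Headline chain: radius-dependent water windows, f_oc bounds from the
  window-width / delivery-variability ratio, the f_pt upper bound, their
  product f_i, and the rescaled galactic ACC count range.
stages: [water, foc, fpt, drake]
water:
  radii: [0.5, 1.0, 2.35]
  freeboard_mode: conservative
foc:
  method: ratio
  radius_small: 0.5
  radius_large: 2.35
  variability: [3.8, 55]
fpt:
  stellar_fraction: 0.33
  large_enough_fraction: 0.5
drake:
  mode: acc_scaled
  base_low: 200
  base_high: 5.0e+7
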