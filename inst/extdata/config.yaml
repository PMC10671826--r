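gamma: 1
p_present: 0.79
eta_alpha: 2
hours_per_worker: 20
contract:
  a: 1.5
  b_ft: 8
  b_pt: 5
travel:
  k_l: 0.5
  k_c: 2
objective:
  lambda1: 1
  lambda3: 1
  lambda4: 1
  lambda6: 0.001
  l_threshold: 0.6
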