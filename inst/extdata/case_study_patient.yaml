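# Reference patient for the case study (units: mm, degrees, mN).
MAD_pre: 41
IPD_pre: 44.6
TH_pre: 12.4
TH_opt: 6.8
delta_a: 32.6
delta_p: 56.8
h_a: 45
h_p: 35
l_a: 18
l_p: 13
B: 500
material:
  c1: 352.4
  c2: 0.1907
  A_ref: 0.197
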