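# weakly-informative joint prior for the trivariate study population
mu0: [0, 0, 0]
tau: 1
m: 3
Lambda:
  - [60, 0, 0]
  - [0, 60, 0]
  - [0, 0, 60]
convention: scale_literal
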