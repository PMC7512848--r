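experiments:
- model: example1
  theta_true: 0.3333
  'n': 200
  reps: 1000
  lambda1: -2.0
  h1:
  - 0.5
  - 1.0
  - 2.0
  lambda2: -2.0
  h2:
  - 0.5
  - 1.0
  - 2.0
  distinct_h: yes
  method: bootstrap
  B: 200
  alphas:
  - 0.05
  - 0.1
  seed: 1
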