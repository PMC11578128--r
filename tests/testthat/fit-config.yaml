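design:
  n_q12: 10
  n_q24: 25
  n_morning: 14
  times_plasma_morning:
  - 0.0
  - 1.0
  - 2.0
  - 4.0
  - 8.0
  times_milk_morning:
  - 0.0
  - 2.0
  - 4.0
  - 8.0
  times_infant_morning:
  - 0.0
  - 4.0
  - 6.0
  times_plasma_evening:
  - 12.0
  - 16.0
  - 20.0
  times_milk_evening:
  - 12.0
  - 16.0
  - 20.0
  times_infant_evening:
  - 12.0
  - 18.0
  visit1_window:
  - 7.0
  - 13.0
  - 43.0
  visit2_window:
  - 36.0
  - 73.5
  - 84.0
  lloq_plasma: 5.0
  lloq_milk: 16.6
  lloq_infant: 5.0
  missingness: 0.07
model:
  theta:
    ka: 1.87
    cl: 19.4
    vc: 184.0
    kcb: 0.245
    rcb: 1.77
  omega:
  - - 0.043681
    - 0.0670639
    - 0.0
  - - 0.0670639
    - 0.583696
    - 0.0
  - - 0.0
    - 0.0
    - 0.025281
  sigma2:
    plasma: 0.146689
    milk: 0.093025
estimation:
  method: laplace
  blq: M1
  se: no
diagnostics:
  n_sim: 500
  bins:
  - 0.0
  - 1.0
  - 3.0
  - 6.0
  - 10.0
  - 14.0
  - 18.0
  - 24.0
seed: 1
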