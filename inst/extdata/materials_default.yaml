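fung:
  anterior:
    c: 8.0
    a_cc: 35.0
    a_rr: 20.0
    a_cr: 10.0
    a_ss: 27.5
  posterior:
    c: 6.0
    a_cc: 30.0
    a_rr: 18.0
    a_cr: 8.0
    a_ss: 24.0
ogden:
  marginal:
    mu: 600.0
    alpha: 12.0
  strut:
    mu: 450.0
    alpha: 10.0
areas:
  anterior_marginal: 0.29
  posterior_marginal: 0.27
  strut: 0.61
tissue:
  thickness_anterior: 0.69
  thickness_posterior: 0.51
  density: 1100.0
  poisson: 0.48
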