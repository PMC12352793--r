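{
  "r_A": 800,
  "r_B": 500,
  "beta": 0.4,
  "rho_A": 0.5,
  "rho_B": 0.5,
  "mu_A": 0.5,
  "mu_B": 0.5,
  "I": 20,
  "C": 5,
  "H": 2,
  "R_A": 0,
  "R_B": 0
}
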