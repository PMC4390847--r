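reactions: ''
species: A
reactor:
  B_T: 63064.0
  b_eps: 0.15
  s_eps:
    A: 0.05
  Dx:
    A: 1.0
  D_ribose: 265000000.0
  lambda: 4.0e-08
task: sweep
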