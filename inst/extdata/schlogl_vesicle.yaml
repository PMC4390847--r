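reactions: X + 2Y <-> 3Y (k=52500, kr=2850); Y <-> Z (k=0.0915, kr=0.00715)
species:
- X
- 'Y'
- Z
reactor:
  B_T: 1000.0
  b_eps: 0.002
  s_eps:
    X: 0.000647
    'Y': 0.0005
    Z: 0.000632
  Dx:
    X: 1.0
    'Y': 1.0
    Z: 1.0
  D_ribose: 265000000.0
  lambda: 4.0e-08
task: steady
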