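reactions: X + Z -> 2Y (k=586); 2Y -> Y + Z (k=926); Y + Z -> Z + W (k=575); Y ->
  W (k=0.0998)
species:
- X
- 'Y'
- Z
- W
reactor:
  B_T: 1000.0
  b_eps: 0.002
  s_eps:
    X: 0.00117
    'Y': 0.0005
    Z: 0.0005
    W: 0.0002
  Dx:
    X: 1.0
    'Y': 1.0
    Z: 1.0
    W: 1.0
  D_ribose: 265000000.0
  lambda: 4.0e-08
task: steady
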