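reactions: X -> Y (k=2.87469599456828); P -> Q (k=0.215314555467906)
species:
- X
- 'Y'
- P
- Q
reactor:
  B_T: 6325.034411358300531
  b_eps: 0.227699388171325
  s_eps:
    X: 0.10781839268169
    'Y': 0.119145867771615
    P: 0.19888452205862
    Q: 0.161684608076966
  Dx:
    X: 43.570100461207652
    'Y': 10.991204142899889
    P: 38.069660286079504
    Q: 123.864152461542574
  D_ribose: 265000000.0
  lambda: 4.0e-08
task: sweep
seed: 101.0
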