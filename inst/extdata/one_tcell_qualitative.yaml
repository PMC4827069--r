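space:
  genotypes:
  - mel
  phenotypes:
    mel:
    - x
    - 'y'
  tcells:
  - zx
  cytokines:
  - w
cancer:
  b:
    x: 3.0
    'y': 3.0
  d:
    x: 1.0
    'y': 1.0
  c:
    x:
      x: 1.0
      'y': 0.3
    'y':
      x: 0.3
      'y': 1.0
  c_b: []
  t_kill:
    x:
      zx: 20.0
  kill_burst:
    x:
      zx:
        w: 2.0
  s_nat:
    x:
      'y': 0.05
    'y':
      x: 0.05
  s_cyt:
    w:
      x:
        'y': 3.0
  mu: {}
  m_law: []
tcells:
  b_T: {}
  d_T:
    zx: 1.0
  t_prod:
    zx:
      x: 5.0
  rep_burst:
    zx:
      w: 1.0
cytokines:
  d_W:
    w: 10.0
K: 200.0
mu_scaling:
  rule: constant
init:
  counts:
    x: 300.0
    zx: 20.0
run:
  t_max: 100.0
  replicates: 50.0
  base_seed: 1.0
  meta:
    name: one_tcell_qualitative
    diffPhenotypes: x
    description: qualitative ACT, one T-cell specificity
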