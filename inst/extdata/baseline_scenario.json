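{
  "scenario": "baseline_novel",
  "n_genes": 8,
  "vdj_n": 500,
  "seed": 42,
  "budget": 10000,
  "bound": 10000,
  "ifn_gamma": true,
  "rescue": true,
  "attack_gene": 2
}
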