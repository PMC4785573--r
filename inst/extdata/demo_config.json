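{
  "seed": 1,
  "out_dir": "famibd_demo_out",
  "simulate": {
    "n_controls": 200,
    "n_cd": 140,
    "n_uc": 133,
    "n_shared": 110,
    "include_nod2": true,
    "rho_total": 35.3,
    "n_rare_per_family": 2
  },
  "ibd": { "min_support": 3, "max_conflicts": 0, "max_af": 0.03 },
  "filter": { "min_quality": 35, "max_af": 0.03, "max_gene_distance": 2 },
  "prs": {}
}
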