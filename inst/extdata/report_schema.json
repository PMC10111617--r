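{
  "title": "mrmediate pipeline report",
  "required": ["software", "version", "seed", "config", "exposure",
               "mediators", "screening", "mediation"],
  "analysis_required": ["pair", "instruments", "estimates", "sensitivity"],
  "estimate_required": ["method", "beta", "se", "pval", "or",
                        "ci_low", "ci_high", "n_snp"]
}
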