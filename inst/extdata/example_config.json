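{
  "seed": 42,
  "n_genes": 1,
  "transcripts_per_gene": 2,
  "exons_per_transcript": 7,
  "cassette_index": 4,
  "n_samples": 200,
  "group_fractions": {"Solid Tissue Normal": 0.5, "Primary Solid Tumor": 0.5},
  "inclusion": {"high_group": "Primary Solid Tumor", "included": 0.9, "excluded": 0.1},
  "noise": 0.15,
  "survival": {"baseline": 0.0008, "effect": 1.2, "censor_max": 2500}
}
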