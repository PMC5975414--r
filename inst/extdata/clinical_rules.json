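[
  {"name": "sample_type", "kind": "passthrough", "field": "sample_type"},
  {"name": "pack_years", "kind": "builtin", "builtin": "pack_years",
   "field": "number_pack_years_smoked"},
  {"name": "survival", "kind": "survival",
   "fields": ["day_to_death", "days_to_last_follow-up"]},
  {"name": "pathology_stage", "kind": "builtin", "builtin": "stage",
   "field": "pathology_stage"},
  {"name": "clinical_stage", "kind": "builtin", "builtin": "stage",
   "field": "clinical_stage"},
  {"name": "masaoka_stage", "kind": "builtin", "builtin": "stage",
   "field": "masaoka_stage"},
  {"name": "risk_factor", "kind": "builtin", "builtin": "lihc_risk",
   "field": "risk_factor"},
  {"name": "alcohol_per_day", "kind": "builtin", "builtin": "alcohol",
   "field": "alcohol_per_day"},
  {"name": "pregnancies", "kind": "builtin", "builtin": "pregnancies",
   "field": "number_of_pregnancies"}
]
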