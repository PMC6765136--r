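{
  "n_polymerase": 6,
  "n_tfiis": 2,
  "n_ccr4": 1,
  "n_xrn1": 5,
  "gene_length": 60,
  "nucleus_radius": 5,
  "cytoplasm_radius": 10,
  "dimensions": 3,
  "radius_tfiis": 3,
  "radius_ccr4": 4,
  "radius_promoter_contact": 2.5,
  "radius_xrn1_promoter": 5,
  "radius_decay": 3,
  "step_polymerase": 1,
  "step_tfiis": 1,
  "step_ccr4": 1,
  "step_xrn1": 1,
  "step_mrna": 1,
  "p_init": 0.025,
  "xrn1_boost": 3,
  "p_backtrack": 0.015,
  "p_inactivate": 0.06,
  "ac_inactivate_scale": 0.1,
  "p_spontaneous_reactivate": 0.08,
  "p_dropoff": 0.03,
  "step_advance": 2,
  "ax_speed_mult": 2,
  "ac_speed_mult": 1,
  "mrna_basal_decay": 0.0005,
  "degradation_ticks": 100,
  "export_rule": "crossing",
  "model": "model1",
  "ccr4_mode": "reactivate",
  "xrn1_feedback": true,
  "imprinting": true,
  "model2_rate_boost": true,
  "burn_in_ticks": 4000,
  "record_ticks": 900,
  "seed": 1
}
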