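# Annualized cost line items for the extraction/distillation recovery
# train: one-off investment in million USD, utilities in million USD per
# year. Payout time and annual operating hours are the evaluation
# assumptions.
investment:
  extractor_column: 0.247
  extractor_tray: 0.015
  extractor_preheater_cooler: 0.123
  dist1_column: 0.128
  dist1_tray: 0.006
  dist1_reboiler: 0.078
  dist1_condenser: 0.069
  dist1_preheater_cooler: 0.083
  dist2_column: 0.094
  dist2_tray: 0.004
  dist2_reboiler: 0.032
  dist2_condenser: 0.061
  dist2_preheater_cooler: 0.003
  dist3_column: 0.055
  dist3_tray: 0.002
  dist3_reboiler: 0.009
  dist3_condenser: 0.022
  dist3_preheater_cooler: 0.001
utility:
  dist1_steam: 0.209
  dist1_coolant: 0.002
  dist2_steam: 0.052
  dist2_coolant: 0.002
  dist3_steam: 0.007
  dist3_coolant: 0.001
payout_years: 5.0
hours_per_year: 8000.0
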