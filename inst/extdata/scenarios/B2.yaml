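name: B2
initial_soil_mg_kg: 70.0
percentile: median
sources:
  - name: air
    rate_g_per_ha_a: 11.0
  - name: gunshot
    rate_g_per_ha_a: 80.0
  - name: fertilizer
    rate_g_per_ha_a: 313.0
soil:
  mixing_depth_m: 0.2
  bulk_density_kg_m3: 1700.0
  washout_rate_per_a: 2.0e-03
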