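name,uptake_factor,uptake_factor_eq,yield_kg_m2_a,intake_adult_kg_d,intake_child_kg_d
cereals,3.0e-4,3.0e-4,0.8,0.283,0.11
potatoes,1.0e-2,3.0e-3,5.0,0.094,0.10
leafy_vegetables,3.0e-3,1.0e-2,3.0,0.318,0.19
other_vegetables,8.0e-4,8.0e-4,3.3,0.144,0.18
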