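name,bmdl_value,bmdl_basis,body_weight_kg,required_margin,population
developmental_neurotoxicity,0.5,dose_ug_per_kg_bw_d,20,1,child
renal_failure,0.63,dose_ug_per_kg_bw_d,60,1,adult
kidney_cancer,519,dose_mg_per_person_d,60,10000,adult
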