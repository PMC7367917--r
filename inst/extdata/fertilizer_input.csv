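scenario,median_g_per_ha_a,p90_g_per_ha_a
A,7.5,9.4
B,313.0,314.6
C,69.5,80.7
D,6.2,7.8
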