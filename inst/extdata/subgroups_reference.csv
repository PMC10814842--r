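name,bw_kg,lp_kg_per_day,fi_kg_per_day,v
general,53.23,0.57,0.045,3
children,16.14,0.366,0.055,3
women_childbearing,52.6,0.297,0.043,3
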