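compound,hr_mg_per_kg,stmr_mg_per_kg
pyraclostrobin,1.88,0.13
cyazofamid,0.78,0.11
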