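compound,residue_mg_per_kg,censored
pyraclostrobin,0.6736,0
pyraclostrobin,0.066,0
pyraclostrobin,0.201,0
pyraclostrobin,0.2778,0
pyraclostrobin,0.2112,0
pyraclostrobin,0.1145,0
pyraclostrobin,0.7974,0
pyraclostrobin,0.116,0
pyraclostrobin,1.465,0
pyraclostrobin,0.1206,0
pyraclostrobin,0.6223,0
pyraclostrobin,2.0213,0
pyraclostrobin,0.0246,1
pyraclostrobin,0.093,0
pyraclostrobin,0.1108,0
pyraclostrobin,0.2789,0
pyraclostrobin,0.0924,0
pyraclostrobin,0.0054,1
pyraclostrobin,0.007,1
pyraclostrobin,0.6338,0
pyraclostrobin,0.09,0
pyraclostrobin,0.0153,1
pyraclostrobin,0.1058,0
pyraclostrobin,0.5584,0
cyazofamid,0.7319,0
cyazofamid,0.0715,0
cyazofamid,0.085,0
cyazofamid,0.0189,1
cyazofamid,0.1743,0
cyazofamid,0.058,0
cyazofamid,0.1735,0
cyazofamid,0.2226,0
cyazofamid,0.3097,0
cyazofamid,0.0598,0
cyazofamid,0.1823,0
cyazofamid,0.0198,1
cyazofamid,0.0502,0
cyazofamid,0.047,1
cyazofamid,0.0098,1
cyazofamid,0.114,0
cyazofamid,0.1352,0
cyazofamid,0.0767,0
cyazofamid,0.2348,0
cyazofamid,0.0532,0
cyazofamid,0.028,1
cyazofamid,0.1696,0
cyazofamid,0.0489,1
cyazofamid,0.4662,0
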