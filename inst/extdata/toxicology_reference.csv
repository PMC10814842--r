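compound,adi,arfd
pyraclostrobin,0.03,0.05
cyazofamid,0.2,0.2
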