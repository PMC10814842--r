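compound,medium,level_mg_per_L,response
pyraclostrobin,solvent,0.05,3.60045
pyraclostrobin,solvent,0.1,7.3516
pyraclostrobin,solvent,0.5,37.3608
pyraclostrobin,solvent,1,74.8723
pyraclostrobin,solvent,5,374.9643
pyraclostrobin,matrix,0.05,4.79745
pyraclostrobin,matrix,0.1,8.7753
pyraclostrobin,matrix,0.5,40.5981
pyraclostrobin,matrix,1,80.3766
pyraclostrobin,matrix,5,398.6046
cyazofamid,solvent,0.05,1.72095
cyazofamid,solvent,0.1,4.0248
cyazofamid,solvent,0.5,22.4556
cyazofamid,solvent,1,45.4941
cyazofamid,solvent,5,229.8021
cyazofamid,matrix,0.05,2.68465
cyazofamid,matrix,0.1,4.9229
cyazofamid,matrix,0.5,22.8289
cyazofamid,matrix,1,45.2114
cyazofamid,matrix,5,224.2714
CCIM,solvent,0.05,3.14725
CCIM,solvent,0.1,7.3312
CCIM,solvent,0.5,40.8028
CCIM,solvent,1,82.6423
CCIM,solvent,5,417.3583
CCIM,matrix,0.05,4.9266
CCIM,matrix,0.1,8.9087
CCIM,matrix,0.5,40.7655
CCIM,matrix,1,80.5865
CCIM,matrix,5,399.1545
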