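compound,spike_mg_per_kg,replicate,measured_mg_per_kg
pyraclostrobin,0.05,1,0.0416372316503433
pyraclostrobin,0.05,2,0.0467379379793005
pyraclostrobin,0.05,3,0.0462552110405482
pyraclostrobin,0.05,4,0.0402500414969845
pyraclostrobin,0.05,5,0.0444631603376211
pyraclostrobin,0.5,1,0.54418411505581
pyraclostrobin,0.5,2,0.461164771013277
pyraclostrobin,0.5,3,0.472079975620966
pyraclostrobin,0.5,4,0.494317209203158
pyraclostrobin,0.5,5,0.517649876267638
pyraclostrobin,2,1,1.75988714226225
pyraclostrobin,2,2,1.68592542218514
pyraclostrobin,2,3,1.65312773170124
pyraclostrobin,2,4,1.84693606873647
pyraclostrobin,2,5,1.63366416517042
cyazofamid,0.05,1,0.0477793704421621
cyazofamid,0.05,2,0.0461372832118796
cyazofamid,0.05,3,0.0452707324079158
cyazofamid,0.05,4,0.0448287328807426
cyazofamid,0.05,5,0.0433480157691587
cyazofamid,0.5,1,0.504660802279628
cyazofamid,0.5,2,0.497789631269497
cyazofamid,0.5,3,0.479858601319763
cyazofamid,0.5,4,0.478208553896364
cyazofamid,0.5,5,0.497397562228721
cyazofamid,2,1,2.04898910918147
cyazofamid,2,2,1.99753783614547
cyazofamid,2,3,1.96857176757632
cyazofamid,2,4,1.8626722166387
cyazofamid,2,5,2.09704049817467
CCIM,0.05,1,0.0507490057125016
CCIM,0.05,2,0.051093228491913
CCIM,0.05,3,0.0486927640020559
CCIM,0.05,4,0.0501562983674398
CCIM,0.05,5,0.0495073071395084
CCIM,0.5,1,0.495470290234656
CCIM,0.5,2,0.52312370193015
CCIM,0.5,3,0.512641635333799
CCIM,0.5,4,0.52793294864741
CCIM,0.5,5,0.507031683438836
CCIM,2,1,2.04393748926408
CCIM,2,2,2.0653007307177
CCIM,2,3,2.04265674003086
CCIM,2,4,2.09444917398548
CCIM,2,5,2.05854967220311
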