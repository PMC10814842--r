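compound,site,day,residue_mg_per_kg,censored
pyraclostrobin,site-A,0,0.68067244558121,0
pyraclostrobin,site-A,3,0.607569898652579,0
pyraclostrobin,site-A,7,0.51310953186469,0
pyraclostrobin,site-A,14,0.383689688638866,0
pyraclostrobin,site-A,21,0.268201302507849,0
pyraclostrobin,site-A,28,0.19483281641465,0
pyraclostrobin,site-B,0,0.479437660916895,0
pyraclostrobin,site-B,3,0.368822523095499,0
pyraclostrobin,site-B,7,0.408992774780789,0
pyraclostrobin,site-B,14,0.302930956753694,0
pyraclostrobin,site-B,21,0.263824270737529,0
pyraclostrobin,site-B,28,0.233216060445093,0
cyazofamid,site-A,0,0.473234575079491,0
cyazofamid,site-A,3,0.266513077778748,0
cyazofamid,site-A,7,0.140099853671292,0
cyazofamid,site-A,14,0.0580065010123786,0
cyazofamid,site-A,21,0.015939030772964,1
cyazofamid,site-A,28,0.00558468805525037,1
cyazofamid,site-B,0,0.290520482911891,0
cyazofamid,site-B,3,0.29668882916149,0
cyazofamid,site-B,7,0.175572206883815,0
cyazofamid,site-B,14,0.0875347599941761,0
cyazofamid,site-B,21,0.0452248440942996,1
cyazofamid,site-B,28,0.0236052816470554,1
CCIM,site-A,0,0.292588990908523,0
CCIM,site-A,3,0.255411530862223,0
CCIM,site-A,7,0.204043120060626,0
CCIM,site-A,14,0.167204439165938,0
CCIM,site-A,21,0.129835215139092,0
CCIM,site-A,28,0.0981931589985695,0
CCIM,site-B,0,0.25476869357546,0
CCIM,site-B,3,0.191493304297768,0
CCIM,site-B,7,0.205852316498915,0
CCIM,site-B,14,0.146485853670207,0
CCIM,site-B,21,0.109835940678276,0
CCIM,site-B,28,0.08950147234434,0
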