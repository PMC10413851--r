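species,method,MUE,MAX,MUE_pct,MAX_pct
uracil,rDSD_j3,10.4,18.1,0.63,0.56
uracil,rDSD,8.3,11.5,0.36,0.41
uracil,PCS,0.9,1.9,0.05,0.09
uracil,B3LYP,25.5,37.4,1.09,1.19
KA,rDSD_j3,9.7,14.2,0.42,0.47
KA,rDSD,5.7,8.5,0.25,0.29
KA,PCS,2.4,5.3,0.08,0.14
KA,B3LYP,29.9,48.9,1.27,1.23
EA,rDSD_j3,10.2,15.7,0.43,0.46
EA,rDSD,6.3,9.5,0.27,0.30
EA,PCS,2.2,5.2,0.07,0.13
EA,B3LYP,28.1,44.1,1.17,1.21
EAc,rDSD_j3,13.3,21.7,0.54,0.55
EAc,rDSD,3.1,7.2,0.38,0.41
EAc,PCS,1.5,2.8,0.05,0.07
EAc,B3LYP,31.2,50.0,1.28,1.29
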