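species,method,MUE,MAX,MUE_pct,MAX_pct
KI,rDSD,6.9,9.9,0.30,0.32
KI,rDSD_CV,1.8,4.2,0.06,0.11
KI,CCF12_j3,8.9,14.6,0.37,0.38
KI,CCF12_j3_CV,1.1,2.1,0.07,0.10
KIc,rDSD,6.7,9.4,0.29,0.32
KIc,rDSD_CV,1.3,3.0,0.04,0.07
KIc,CCF12_j3,8.7,14.5,0.36,0.37
KIc,CCF12_j3_CV,0.8,2.0,0.03,0.05
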