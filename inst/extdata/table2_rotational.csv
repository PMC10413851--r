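species,method,B_a,B_b,B_c
KI,SE,3877.6,2037.3,1335.7
KI,rDSD,3867.7,2030.7,1331.6
KI,rDSD_CV,3881.8,2036.2,1335.6
KI,CCF12_j3,3863.0,2030.2,1330.8
KI,CCF12_j3_CV,3877.7,2035.2,1334.7
KIc,SE,3889.7,2022.8,1330.9
KIc,rDSD,3880.3,2016.3,1326.8
KIc,rDSD_CV,3892.7,2023.2,1331.3
KIc,CCF12_j3,3875.2,2016.0,1326.1
KIc,CCF12_j3_CV,3887.7,2023.0,1330.6
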