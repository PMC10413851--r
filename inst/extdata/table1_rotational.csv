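species,method,B_a,B_b,B_c
uracil,SE,3913.3,2035.2,1338.9
uracil,rDSD_j3,3895.2,2022.2,1331.2
uracil,rDSD,3901.8,2026.8,1333.9
uracil,PCS,3913.3,2033.3,1338.1
uracil,B3LYP,3875.9,2010.9,1324.0
KA,SE,3899.0,2034.4,1338.2
KA,rDSD_j3,3884.8,2025.9,1331.9
KA,rDSD,3890.5,2029.7,1334.3
KA,PCS,3904.3,2035.9,1338.5
KA,B3LYP,3850.9,1992.1,1312.9
EA,SE,3979.5,2020.0,1341.1
EA,rDSD_j3,3963.8,2011.3,1334.9
EA,rDSD,3970.4,2014.6,1337.1
EA,PCS,3984.7,2020.9,1341.5
EA,B3LYP,3935.4,1996.1,1324.9
EAc,SE,3920.1,2040.5,1342.7
EAc,rDSD_j3,3898.4,2029.6,1335.5
EAc,rDSD,3904.1,2033.3,1337.7
EAc,PCS,3917.3,2039.6,1342.0
EAc,B3LYP,3870.1,2014.3,1325.4
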