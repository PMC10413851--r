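species,block,B_a,B_b,B_c
EA,computed,3955.4,2009.3,1332.6
EAc,computed,3891.9,2026.5,1333.0
KA,computed,3875.2,2026.0,1330.4
KI,computed,3851.0,2024.5,1327.6
KIc,computed,3863.0,2011.2,1323.3
EA,experimental,3951.85325,2008.95802,1332.47228
EAc,experimental,3889.46510,2026.31804,1332.86951
KA,experimental,3871.54618,2024.97804,1330.33627
KI,experimental,3848.18174,2026.31068,1327.99167
KIc,experimental,3861.2966,2011.41032,1323.19999
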