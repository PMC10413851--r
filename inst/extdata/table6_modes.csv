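mode,label,omega_b3_harm,nu_b3_anh,omega_rdsd_harm,hybrid,intensity,exp_freq,exp_intensity
1,nu(OH),3715,3525,3793,3603,99,3592,168
2,nu(asNH2),3709,3560,3739,3590,46,3564,98
3,nu(sNH2),3588,3450,3608,3470,71,3446,154
4,nu(C5H),3217,3090,3223,3096,5,,
5,nu(C6H),3184,3062,3183,3063,14,,
6,nu(C5C6),1674,1625,1671,1623,565,1622,645
7,beta(scNH2),1651,1607,1643,1599,12,1589,64
8,nu(N3C4),1616,1570,1625,1579,256,1570,52
9,beta(C5H),1531,1494,1534,1497,36,1496,73
10,nu(CO),1476,1440,1478,1442,408,1427,285
11,nu(C5C6),1408,1383,1410,1385,46,,
12,beta(C6H),1357,1317,1353,1313,173,1320,72
13,beta(OH),1311,1279,1291,1259,27,,
14,nu(N1C2),1250,1216,1250,1216,34,1196,124
15,beta(C5H),1137,1115,1133,1111,39,1110,29
16,beta(roNH2),1106,1067,1106,1067,43,1083,60
17,gamma(C6H),1008,989,1008,989,9,,
18,beta(R1),995,973,1006,984,1,980,30
19,nu(C4C5),992,973,995,976,16,955,3
20,gamma(CO),816,810,827,821,51,807,69
21,gamma(C5H),796,784,804,792,1,,
22,beta(R1),792,778,796,782,7,781,30
23,gamma(CO),716,716,728,728,4,710,8
24,beta(R3),601,593,601,593,1,,
25,tau(OH),563,550,562,551,28,557,21
26,beta(R2),571,522,562,523,71,520,221
27,tau(toNH2),511,489,511,489,15,507,67
28,tau(toNH2),491,460,493,462,12,498,42
29,tau(R3),450,444,451,445,16,443,13
30,beta(CN8),343,329,342,328,45,343,11
31,tau(invNH2),321,-216,348,348,219,235,244
32,tau(invNH2),220,216,220,216,12,,
33,tau(R2),186,185,187,186,1,,
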