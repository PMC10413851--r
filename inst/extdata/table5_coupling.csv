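parameter,block,EA,EAc,KA,KI,KIc
chi_aa_N1,computed,-2.6818,-2.8574,1.6092,1.8615,2.1259
chi_bb_N1,computed,1.1516,1.0054,1.4602,2.0432,1.7903
chi_cc_N1,computed,1.5301,1.8520,-3.0694,-3.9047,-3.9162
chi_aa_N3,computed,2.2536,2.2343,2.5229,2.1311,1.8548
chi_bb_N3,computed,-3.7073,-3.4322,-3.5884,1.6010,2.0767
chi_cc_N3,computed,1.4537,1.1980,1.0654,-3.7321,-3.9315
chi_aa_N8,computed,2.1936,2.1865,2.1923,1.8367,-2.1965
chi_bb_N8,computed,1.9946,2.0231,1.9159,-3.1411,0.9632
chi_cc_N8,computed,-4.1882,-4.2096,-4.1082,1.3044,1.2333
mu_a,computed,-2.9632,-4.4160,-4.4651,-0.6290,0.6886
mu_b,computed,1.3316,-0.9458,4.6748,4.6635,2.3435
mu_c,computed,-0.6243,-0.6612,-0.4753,0.0000,0.0000
chi_aa_N1,experimental,-2.6373,-2.8007,1.6211,1.8518,1.898
chi_bb_N1,experimental,1.1672,1.0340,1.4772,2.0545,2.104
chi_cc_N1,experimental,1.4701,1.7667,-3.0983,-3.9063,-4.002
chi_aa_N3,experimental,2.2619,2.2371,2.5217,2.1383,2.105
chi_bb_N3,experimental,-3.6570,-3.3890,-3.5140,1.6064,1.764
chi_cc_N3,experimental,1.3951,1.1519,0.9923,-3.7448,-3.870
chi_aa_N8,experimental,2.2167,2.2237,2.1802,1.8033,-2.091
chi_bb_N8,experimental,1.9511,1.9832,1.8429,-3.1572,0.940
chi_cc_N8,experimental,-4.1678,-4.2069,-4.0231,1.3539,1.151
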