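element,isotope,mass,principal
H,1,1.00782503207,1
H,2,2.01410177812,0
C,12,12.0,1
C,13,13.00335483507,0
N,14,14.00307400443,1
N,15,15.00010889888,0
O,16,15.99491461957,1
O,17,16.99913175650,0
O,18,17.99915961286,0
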