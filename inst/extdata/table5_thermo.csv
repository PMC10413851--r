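species,block,dG
EA,computed,0
EAc,computed,247
KA,computed,161
KI,computed,579
KIc,computed,1136
EA,experimental,0
EAc,experimental,165
KA,experimental,40
KI,experimental,290
KIc,experimental,
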