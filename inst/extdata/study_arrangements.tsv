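chromosome	arrangement
A	A_ST
A	A_1
A	A_2
J	J_ST
J	J_1
U	U_ST
U	U_1+2
U	U_1+2+8
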