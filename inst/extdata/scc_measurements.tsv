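label	upstream	stop	downstream	readthrough_percent
WT	AACGGCAUCG	UGA	CUAGAAGCAG	4.34
stop_UAA	AACGGCAUCG	UAA	CUAGAAGCAG	0.06
stop_UAG	AACGGCAUCG	UAG	CUAGAAGCAG	0.05
p4_C_A	AACGGCAUCG	UGA	AUAGAAGCAG	0.07
p4_C_G	AACGGCAUCG	UGA	GUAGAAGCAG	0.06
p4_C_U	AACGGCAUCG	UGA	UUAGAAGCAG	0.08
p5_U_A	AACGGCAUCG	UGA	CAAGAAGCAG	0.62
p5_U_C	AACGGCAUCG	UGA	CCAGAAGCAG	0.48
p5_U_G	AACGGCAUCG	UGA	CGAGAAGCAG	0.55
p6_A_C	AACGGCAUCG	UGA	CUCGAAGCAG	0.44
p6_A_G	AACGGCAUCG	UGA	CUGGAAGCAG	0.78
p6_A_U	AACGGCAUCG	UGA	CUUGAAGCAG	0.58
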