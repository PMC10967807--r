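# EMBOSS pKa set, provided as an alternative to the Bjellqvist defaults.
site	group	pka
NTERM	nterm	8.60
CTERM	cterm	3.60
D	negative	3.90
E	negative	4.10
C	negative	8.50
Y	negative	10.10
H	positive	6.50
K	positive	10.80
R	positive	12.50
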