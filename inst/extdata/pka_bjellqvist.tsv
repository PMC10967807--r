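# Bjellqvist pKa set (the ProtParam convention). 'group' is one of
# nterm, cterm, positive, negative; side-chain rows are keyed by residue.
site	group	pka
NTERM	nterm	7.50
CTERM	cterm	3.55
D	negative	4.05
E	negative	4.45
C	negative	9.00
Y	negative	10.00
H	positive	5.98
K	positive	10.00
R	positive	12.00
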