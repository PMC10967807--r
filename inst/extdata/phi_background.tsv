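# Phi-segment (disordered linker) background amino-acid composition used by
# the synthetic-sequence generator: glycine/threonine-rich, enriched in
# charged and polar residues, poor in aromatic and aliphatic hydrophobics,
# so that generated proteins are hydrophilic (negative GRAVY) and predicted
# disordered (negative fold index) like real dehydrins.
residue	freq
G	0.140
T	0.100
E	0.090
K	0.090
S	0.090
D	0.070
P	0.060
N	0.050
A	0.050
H	0.050
Q	0.040
R	0.040
V	0.025
L	0.025
M	0.020
I	0.020
Y	0.020
F	0.010
W	0.005
C	0.005
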