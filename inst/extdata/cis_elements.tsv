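# Cis-regulatory element catalog: canonical PlantCARE-style consensus strings
# (IUPAC DNA alphabet; several comma-separated variants allowed per element).
# The catalog is data, not code: edit or replace it to match a different
# motif collection.
name	category	consensus
ABRE	HORMONE	ACGTG
CGTCA-motif	HORMONE	CGTCA
TGACG-motif	HORMONE	TGACG
AuxRR-core	HORMONE	GGTCCAT
TGA-element	HORMONE	AACGAC
SARE	HORMONE	TTCGACCATCTT
P-box	HORMONE	CCTTTTG
TATC-box	HORMONE	TATCCCA
GARE-motif	HORMONE	TCTGTTG
G-box	LIGHT	CACGTG
Box 4	LIGHT	ATTAAT
LTR	STRESS	CCGAAA
ARE	STRESS	AAACCA
as-1	STRESS	TGACG
W box	STRESS	TTGACC
DRE core	STRESS	GCCGAC
MYB	STRESS	CAACAG,TAACCA
MYC	STRESS	CATGTG,CATTTG
MBS	STRESS	CAACTG
TC-rich repeats	STRESS	ATTTTCTTCA
WUN-motif	STRESS	AAATTTCCT
WRE3	STRESS	CCACCT
circadian	STRESS	CAANNNNATC
CAT-box	DEVELOPMENT	GCCACT
RY-element	DEVELOPMENT	CATGCATG
GCN4_motif	DEVELOPMENT	TGAGTCA
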