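one	three	mass
A	ALA	71.0788
R	ARG	156.1875
N	ASN	114.1038
D	ASP	115.0886
C	CYS	103.1388
Q	GLN	128.1307
E	GLU	129.1155
G	GLY	57.0519
H	HIS	137.1411
I	ILE	113.1594
L	LEU	113.1594
K	LYS	128.1741
M	MET	131.1926
F	PHE	147.1766
P	PRO	97.1167
S	SER	87.0782
T	THR	101.1051
W	TRP	186.2132
Y	TYR	163.1760
V	VAL	99.1326
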