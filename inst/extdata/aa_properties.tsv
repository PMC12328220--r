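aa	name3	max_sasa	logp	class	mw
A	ALA	129.0	0.31	aliphatic	89.09
R	ARG	274.0	-1.01	basic	174.20
N	ASN	195.0	-0.60	polar	132.12
D	ASP	193.0	-0.77	acidic	133.10
C	CYS	167.0	1.54	C	121.16
Q	GLN	225.0	-0.22	polar	146.15
E	GLU	223.0	-0.64	acidic	147.13
G	GLY	104.0	0.00	G	75.07
H	HIS	224.0	0.13	basic	155.15
I	ILE	197.0	1.80	aliphatic	131.17
L	LEU	201.0	1.70	aliphatic	131.17
K	LYS	236.0	-0.99	basic	146.19
M	MET	224.0	1.23	aliphatic	149.21
F	PHE	240.0	1.79	aromatic	165.19
P	PRO	159.0	0.72	P	115.13
S	SER	155.0	-0.04	polar	105.09
T	THR	172.0	0.26	polar	119.12
W	TRP	285.0	2.25	aromatic	204.23
Y	TYR	263.0	0.96	aromatic	181.19
V	VAL	174.0	1.22	aliphatic	117.15
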