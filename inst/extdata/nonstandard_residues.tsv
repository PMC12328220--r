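resid	parent
MSE	M
SEC	C
PYL	K
CSO	C
CSD	C
CME	C
OCS	C
SEP	S
TPO	T
PTR	Y
HYP	P
MLY	K
M3L	K
KCX	K
LLP	K
PCA	E
FME	M
HIC	H
NEP	H
CGU	E
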